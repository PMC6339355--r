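concentration_mg_per_ml,peak_area
0,12
0.00002,105
0.0001,492
0.0005,2488
0.002,10060
0.01,49950
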