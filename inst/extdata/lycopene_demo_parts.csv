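part_id,name,part_class,native_host,sequence,strength_value,strength_units,reference_standard
prom1,Psyn-med,promoter,E. coli,TTGACGGCTAGCTCAGTCCTAGGTACAGTGCTAGC,0.38,RPU,J23101
prom2,Psyn-vlow,promoter,E. coli,TTGACAGCTAGCTCAGTCCTAGGGATTGTGCTAGC,0.06,RPU,J23101
prom3,Psyn-low,promoter,E. coli,CTGATAGCTAGCTCAGTCCTAGGGATTATGCTAGC,0.12,RPU,J23101
prom4,Psyn-midlow,promoter,E. coli,TTTACGGCTAGCTCAGTCCTAGGTATTATGCTAGC,0.21,RPU,J23101
prom5,Psyn-mid,promoter,E. coli,TTGACAGCTAGCTCAGTCCTAGGTACTGTGCTAGC,0.55,RPU,J23101
rbsL,RBS-weak,rbs,E. coli,TCACACAGGAAACC,0.30,relative units,B0034
rbsM,RBS-medium,rbs,E. coli,AAAGAGGAGAAATA,1.00,relative units,B0034
rbsH,RBS-strong,rbs,E. coli,TAAGGAGGTAAAAA,2.40,relative units,B0034
crtE,GGPP synthase,cds,Pantoea-like (synthetic),ATGGTCAGCGGTAGCAAACCGTTTGATCTGATTCTGCACGCACCGACCGAAGAATAA,,,
crtB,phytoene synthase,cds,Pantoea-like (synthetic),ATGAACAATCCGTCTCTGCTGAATCATGCCGTTGAAACCATGGCAGTTGGTAGCTAA,,,
crtI,phytoene desaturase,cds,Pantoea-like (synthetic),ATGAAACCGACTACGGTAATTGGTGCAGGCTTTGGTGGCCTGGCACTGGCAATTTAA,,,
term1,L3S2P21-like terminator,terminator,E. coli,CTCGGTACCAAATTCCAGAAAAGAGGCCTCCCGAAAGGGG,,,
lnkL,linker-RBS-weak,linker,synthetic,GGCTCGTCACACAGGAAACCGGTTCAGGTGGAGGTTCTGGAGGTG,,,
lnkM,linker-RBS-medium,linker,synthetic,GGCTCGAAAGAGGAGAAATAGGTTCAGGTGGAGGTTCTGGAGGTG,,,
lnkH,linker-RBS-strong,linker,synthetic,GGCTCGTAAGGAGGTAAAAAGGTTCAGGTGGAGGTTCTGGAGGTG,,,
p15A_kan,p15A-KanR backbone,backbone,E. coli,GGTTATCCACAGAATCAGGGGATAACGCAGGAAAGAACATG,,,
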