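plate_name,well,content_id,concentration,units
parts_1,A1,prom1,76,nM
parts_1,A2,prom2,76,nM
parts_1,A3,prom3,76,nM
parts_1,A4,prom4,76,nM
parts_1,A5,prom5,76,nM
parts_1,B1,rbsL,76,nM
parts_1,B2,rbsM,76,nM
parts_1,B3,rbsH,76,nM
parts_1,C1,crtE,76,nM
parts_1,C2,crtB,76,nM
parts_1,C3,crtI,76,nM
parts_1,D1,term1,76,nM
parts_1,D2,p15A_kan,76,nM
parts_1,E1,lnkL,1,uM
parts_1,E2,lnkM,1,uM
parts_1,E3,lnkH,1,uM
parts_1,H12,master_mix,,
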