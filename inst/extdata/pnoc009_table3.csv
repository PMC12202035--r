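subject,ced_number,gad_mM,vi_mL,duration_min,tumor_cm3,vd_cm3,total_vd_cm3,covered_cm3,coverage_pct
PNOC009-1,1,2.0,2,236,45.1,7.6,7.6,7.5,16.6
PNOC009-2,1,2.0,3,416,23.9,9.8,12.2,10.3,42.9
PNOC009-2,2,2.0,3,350,23.9,7.2,,,
PNOC009-3,1,2.0,3,335,26.7,7.9,11.2,10.6,39.7
PNOC009-3,2,1.0,2,244,26.7,5.8,,,
PNOC009-4,1,0.5,3,419,21.1,5,16.4,13.5,63.7
PNOC009-4,2,0.5,3,359,21.1,6.4,,,
PNOC009-4,3,0.5,3,344,21.1,6.9,,,
PNOC009-4,4,0.5,3,460,21.1,5.5,,,
PNOC009-4,5,0.1,3,377,21.1,0.7,,,
PNOC009-5,1,0.5,3,417,32.4,7.0,11.7,10.1,31.3
PNOC009-5,2,0.5,3,387,32.4,5.4,,,
PNOC009-6,1,0.5,3,357,24.4,5.6,5.6,4.4,17.9
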