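metric,nutrient,est0,se0,lcl0,ucl0,est1,se1,lcl1,ucl1,sig1,est2,se2,lcl2,ucl2,sig2
pct_above_AI,pfa_18_3_g,75.6,1.5,72.7,78.6,76.7,1.5,73.8,79.6,none,77.6,1.5,74.7,80.6,none
pct_above_AI,choline_mg,22.6,0.9,20.9,24.3,43.6,1.2,41.4,45.9,vs_baseline,57.8,2.8,52.4,63.2,vs_scenario1
pct_below_EAR,phosphorus_mg,13.6,1.1,11.4,15.8,10.8,1.1,8.7,12.9,vs_baseline,8.3,0.9,6.5,10.1,vs_scenario1
pct_below_EAR,protein_g,0.5,0.2,0.1,0.8,0.3,0.1,0.003,0.5,none,0.2,0.1,0.0,0.3,none
pct_below_EAR,riboflavin_mg,0.9,0.3,0.3,1.4,0.5,0.2,0.1,0.9,none,0.3,0.1,0.01,0.6,none
pct_below_EAR,vit_a_rae_mcg,23.2,1.4,20.6,25.9,18.7,1.4,16.1,21.5,vs_baseline,14.8,1.2,12.5,17.1,vs_scenario1
pct_below_EAR,vit_d_mcg,92,0.7,90.6,93.4,89.6,0.9,88.0,91.3,vs_baseline,86.1,0.9,84.2,87.9,vs_scenario1
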