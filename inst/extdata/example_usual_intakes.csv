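table,nutrient,baseline,se0,plus1,flag1,se1,plus2,flag2,se2
t1,calcium_mg,1023,10,1039,none,11,1054,none,11
t1,carbohydrate_g,244,2,244,none,2,245,none,2
t1,cholesterol_mg,214,2,319,ge20,3,421,ge20,3
t1,fiber_g,13.9,0.1,13.9,none,0.1,13.8,none,0.1
t1,energy_kcal,1851,15,1891,none,15,1931,none,14
t1,energy_sat_fat_pct,11.7,0.1,11.9,none,0.1,12.1,none,0.1
t1,folate_dfe_mcg,499,6,510,none,6,519,none,6
t1,iron_mg,13.7,0.2,14.2,none,0.2,14.7,none,0.2
t1,lutein_zeaxanthin_mcg,769,17,907,ge20,17,1060,ge20,19
t1,magnesium_mg,231,2,234,none,2,238,none,2
t1,niacin_mg,20.8,0.2,20.8,none,0.2,20.9,none,0.2
t1,pantothenic_acid_mg,28.3,0.3,31.5,ge10,0.3,34.8,ge20,0.4
t1,pfa_18_2_g,13.7,0.2,14.1,none,0.2,14.6,none,0.2
t1,pfa_18_3_g,1.3,0.02,1.4,none,0.02,1.4,none,0.02
t1,pfa_20_5_g,0.01,0.0003,0.01,none,0.0003,0.01,none,0.0003
t1,pfa_22_6_g,0.02,0.0008,0.04,ge20,0.001,0.06,ge20,0.001
t1,phosphorus_mg,1247,10,1302,none,10,1359,none,10
t1,potassium_mg,2146,17,2185,none,16,2222,none,16
t1,protein_g,66.8,0.6,70.2,none,0.6,73.7,ge10,0.6
t1,riboflavin_mg,1.9,0.02,2.1,ge10,0.02,2.2,ge10,0.02
t1,selenium_mcg,93.9,1,102,ge10,1,111,ge20,1
t1,sodium_mg,2924,27,3046,none,27,3165,none,27
t1,thiamin_mg,1.5,0.01,1.5,none,0.02,1.53,none,0.01
t1,choline_mg,248,2,314,ge20,3,379,ge20,3
t1,total_fat_g,69.8,0.6,72.3,none,0.7,75,none,0.7
t1,mufa_g,23.6,0.3,24.6,none,0.3,25.6,none,0.3
t1,pufa_g,15.4,0.2,15.9,none,0.2,16.4,none,0.2
t1,sat_fat_g,24.6,0.3,25.4,none,0.3,26.3,none,0.3
t1,sugars_g,115,1,115,none,1,115,none,1
t1,trans_fat_g,1.9,0.03,1.9,none,0.03,2,none,0.03
t1,vit_a_rae_mcg,594,8,640,none,9,683,ge10,9
t1,vit_b12_mcg,4.7,0.1,4.9,none,0.1,5.1,none,0.1
t1,vit_b6_mg,1.7,0.02,1.7,none,0.02,1.8,none,0.02
t1,vit_c_mg,74.2,1.7,74.2,none,1.7,74.1,none,1.7
t1,vit_d_mcg,5.7,0.1,6.3,ge10,0.1,6.8,ge10,0.1
t1,vit_e_mg,6.9,0.1,7.2,none,0.1,7.5,none,0.1
t1,vit_k_mcg,64.8,1.3,64.7,none,1.3,64.9,none,1.3
t1,zinc_mg,9.8,0.1,10.1,none,0.1,10.5,none,0.1
t2,calcium_mg,1326,53,1341,none,53,1356,none,52
t2,carbohydrate_g,252,12,252,none,11,253,none,11
t2,cholesterol_mg,234,20,339,ge20,17,444,ge20,14
t2,fiber_g,16.3,1,16.3,none,1,16.3,none,1
t2,energy_kcal,1879,76,1924,none,75,1969,none,73
t2,energy_sat_fat_pct,11.1,0.5,11.5,none,0.5,11.7,none,0.5
t2,folate_dfe_mcg,555,37,565,none,37,576,none,36
t2,iron_mg,15.1,1,15.7,none,1.1,16.2,none,1.1
t2,lutein_zeaxanthin_mcg,995,126,1122,ge10,113,1279,ge20,121
t2,magnesium_mg,274,12,277,none,12,280,none,12
t2,niacin_mg,20.7,1.2,20.8,none,1.2,20.8,none,1.2
t2,pantothenic_acid_mg,36.2,1.7,39.5,none,1.7,42.8,ge10,1.7
t2,pfa_18_2_g,13.1,0.7,13.5,none,0.7,14.1,none,0.7
t2,pfa_18_3_g,1.3,0.1,1.3,none,0.1,1.3,none,0.1
t2,pfa_20_5_g,0.01,0.0009,0.01,none,0.0009,0.01,none,0.0009
t2,pfa_22_6_g,0.02,0.005,0.04,ge20,0.003,0.05,ge20,0.003
t2,phosphorus_mg,1523,59,1579,none,61,1632,none,59
t2,potassium_mg,2683,112,2721,none,116,2758,none,110
t2,protein_g,76.1,3.3,79.8,none,3.3,83.1,none,3.2
t2,riboflavin_mg,2.4,0.1,2.5,none,0.1,2.6,none,0.1
t2,selenium_mcg,108,6,116,none,6,125,none,6
t2,sodium_mg,2862,128,2990,none,125,3104,none,121
t2,thiamin_mg,1.5,0.1,1.6,none,0.1,1.6,none,0.1
t2,choline_mg,312,16,378,ge20,14,446,ge20,10
t2,total_fat_g,66.3,3.4,68.9,none,3.3,71.4,none,3.3
t2,mufa_g,21.9,1.3,22.9,none,1.3,23.9,none,1.3
t2,pufa_g,14.7,0.8,15.3,none,0.8,15.9,none,0.8
t2,sat_fat_g,23.6,1.4,24.5,none,1.4,25.3,none,1.3
t2,sugars_g,122,6,121,none,6,121,none,6
t2,trans_fat_g,1.8,0.1,1.8,none,0.1,1.8,none,0.1
t2,vit_a_rae_mcg,766,39,805,none,35,862,ge10,36
t2,vit_b12_mcg,5.7,0.2,5.9,none,0.2,6.1,none,0.2
t2,vit_b6_mg,1.7,0.1,1.8,none,0.1,1.8,none,0.1
t2,vit_c_mg,104,13,104,none,13,104,none,13
t2,vit_d_mcg,8.7,0.5,9.2,none,0.5,9.8,ge10,0.5
t2,vit_e_mg,7.2,0.6,7.4,none,0.6,7.7,none,0.6
t2,vit_k_mcg,79.3,13.8,79.4,none,13.8,79.4,none,13.7
t2,zinc_mg,11,0.5,11.3,none,0.5,11.7,none,0.5
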