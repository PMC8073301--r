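# Nutrient profile of one large (50 g) whole egg = 1 oz eq protein foods.
# Values follow standard whole-egg food-composition references; total choline
# (147 mg) and lutein + zeaxanthin (250 mcg) are the normative per-egg
# constants used by the scenario engine. Units match the package nutrient
# dictionary.
version: 1
nutrients:
  calcium_mg: 28.0
  carbohydrate_g: 0.36
  cholesterol_mg: 186.0
  fiber_g: 0.0
  energy_kcal: 71.5
  folate_dfe_mcg: 23.5
  iron_mg: 0.88
  lutein_zeaxanthin_mcg: 250.0
  magnesium_mg: 6.0
  niacin_mg: 0.04
  pantothenic_acid_mg: 0.77
  pfa_18_2_g: 0.8
  pfa_18_3_g: 0.02
  pfa_20_5_g: 0.0
  pfa_22_6_g: 0.03
  phosphorus_mg: 99.0
  potassium_mg: 69.0
  protein_g: 6.3
  riboflavin_mg: 0.23
  selenium_mcg: 15.4
  sodium_mg: 71.0
  thiamin_mg: 0.02
  choline_mg: 147.0
  total_fat_g: 4.8
  mufa_g: 1.8
  pufa_g: 0.96
  sat_fat_g: 1.6
  sugars_g: 0.19
  trans_fat_g: 0.02
  vit_a_rae_mcg: 80.0
  vit_b12_mcg: 0.45
  vit_b6_mg: 0.09
  vit_c_mg: 0.0
  vit_d_mcg: 1.0
  vit_e_mg: 0.53
  vit_k_mcg: 0.15
  zinc_mg: 0.65
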