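# Dietary Reference Intake values used by the adequacy module, for the
# nutrients reported in the adequacy tables. EARs (Estimated Average
# Requirement) and AIs (Adequate Intake) follow the Institute of Medicine /
# National Academies DRI reports for ages 1-18; protein EARs (g/kg/day) are
# collapsed to absolute g/day using the DRI reference body weights per band.
# Units match the package nutrient dictionary. This file is configuration:
# replace it to analyze other nutrients or updated reference values.
version: 1
references:
  - nutrient: phosphorus_mg
    reference_type: EAR
    bands:
      - {sex: both, age_min: 1, age_max: 3, value: 380}
      - {sex: both, age_min: 4, age_max: 8, value: 405}
      - {sex: both, age_min: 9, age_max: 18, value: 1055}
  - nutrient: protein_g
    reference_type: EAR
    bands:
      - {sex: both, age_min: 1, age_max: 3, value: 10.4}
      - {sex: both, age_min: 4, age_max: 8, value: 15.2}
      - {sex: male, age_min: 9, age_max: 13, value: 27.4}
      - {sex: female, age_min: 9, age_max: 13, value: 28.1}
      - {sex: male, age_min: 14, age_max: 18, value: 44.5}
      - {sex: female, age_min: 14, age_max: 18, value: 38.3}
  - nutrient: riboflavin_mg
    reference_type: EAR
    bands:
      - {sex: both, age_min: 1, age_max: 3, value: 0.4}
      - {sex: both, age_min: 4, age_max: 8, value: 0.5}
      - {sex: both, age_min: 9, age_max: 13, value: 0.8}
      - {sex: male, age_min: 14, age_max: 18, value: 1.1}
      - {sex: female, age_min: 14, age_max: 18, value: 0.9}
  - nutrient: vit_a_rae_mcg
    reference_type: EAR
    bands:
      - {sex: both, age_min: 1, age_max: 3, value: 210}
      - {sex: both, age_min: 4, age_max: 8, value: 275}
      - {sex: male, age_min: 9, age_max: 13, value: 445}
      - {sex: female, age_min: 9, age_max: 13, value: 420}
      - {sex: male, age_min: 14, age_max: 18, value: 630}
      - {sex: female, age_min: 14, age_max: 18, value: 485}
  - nutrient: vit_d_mcg
    reference_type: EAR
    bands:
      - {sex: both, age_min: 1, age_max: 18, value: 10}
  - nutrient: choline_mg
    reference_type: AI
    bands:
      - {sex: both, age_min: 1, age_max: 3, value: 200}
      - {sex: both, age_min: 4, age_max: 8, value: 250}
      - {sex: both, age_min: 9, age_max: 13, value: 375}
      - {sex: male, age_min: 14, age_max: 18, value: 550}
      - {sex: female, age_min: 14, age_max: 18, value: 400}
  - nutrient: pfa_18_3_g
    reference_type: AI
    bands:
      - {sex: both, age_min: 1, age_max: 3, value: 0.7}
      - {sex: both, age_min: 4, age_max: 8, value: 0.9}
      - {sex: male, age_min: 9, age_max: 13, value: 1.2}
      - {sex: female, age_min: 9, age_max: 13, value: 1.0}
      - {sex: male, age_min: 14, age_max: 18, value: 1.6}
      - {sex: female, age_min: 14, age_max: 18, value: 1.1}
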