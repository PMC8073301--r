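# USDA CACFP breakfast component minimums by age band (2017 meal patterns).
# Milk: fluid ounces of an allowed milk type; fruit_vegetable and grain:
# ounce equivalents. Age bands partition 1-18 years per component.
version: 1
milk:
  - {age_min: 1, age_max: 1, min_fl_oz: 4, allowed: [{fat_level: whole, flavored: false}]}
  - {age_min: 2, age_max: 2, min_fl_oz: 4, allowed: [{fat_level: lowfat_1pct, flavored: false},
                                                     {fat_level: skim, flavored: false}]}
  - {age_min: 3, age_max: 5, min_fl_oz: 6, allowed: [{fat_level: lowfat_1pct, flavored: false},
                                                     {fat_level: skim, flavored: false}]}
  - {age_min: 6, age_max: 18, min_fl_oz: 8, allowed: [{fat_level: lowfat_1pct, flavored: false},
                                                      {fat_level: skim, flavored: false},
                                                      {fat_level: skim, flavored: true}]}
fruit_vegetable:
  - {age_min: 1, age_max: 2, min_oz_eq: 0.25}
  - {age_min: 3, age_max: 18, min_oz_eq: 0.5}
grain:
  - {age_min: 1, age_max: 5, min_oz_eq: 0.5}
  - {age_min: 6, age_max: 18, min_oz_eq: 1.0}
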