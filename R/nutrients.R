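# Canonical nutrient dictionary: 37 keys, units as reported in national
# dietary surveillance tables. Energy is a key like any other; the saturated
# fat %-of-energy figure is derived, never stored.

.NUTRIENTS <- tibble::tribble(
  ~key,                   ~label,                                ~unit,
  "calcium_mg",           "Calcium",                             "mg",
  "carbohydrate_g",       "Carbohydrates",                       "g",
  "cholesterol_mg",       "Cholesterol",                         "mg",
  "fiber_g",              "Dietary Fiber",                       "g",
  "energy_kcal",          "Energy",                              "kcal",
  "folate_dfe_mcg",       "Folate DFE",                          "mcg",
  "iron_mg",              "Iron",                                "mg",
  "lutein_zeaxanthin_mcg","Lutein + Zeaxanthin",                 "mcg",
  "magnesium_mg",         "Magnesium",                           "mg",
  "niacin_mg",            "Niacin",                              "mg",
  "pantothenic_acid_mg",  "Pantothenic Acid",                    "mg",
  "pfa_18_2_g",           "PFA 18:2 (Octadecadienoic)",          "g",
  "pfa_18_3_g",           "PFA 18:3 (Octadecatrienoic)",         "g",
  "pfa_20_5_g",           "PFA 20:5 (Eicosapentaenoic)",         "g",
  "pfa_22_6_g",           "PFA 22:6 (Docosahexaenoic)",          "g",
  "phosphorus_mg",        "Phosphorus",                          "mg",
  "potassium_mg",         "Potassium",                           "mg",
  "protein_g",            "Protein",                             "g",
  "riboflavin_mg",        "Riboflavin",                          "mg",
  "selenium_mcg",         "Selenium",                            "mcg",
  "sodium_mg",            "Sodium",                              "mg",
  "thiamin_mg",           "Thiamin",                             "mg",
  "choline_mg",           "Total Choline",                       "mg",
  "total_fat_g",          "Total Fat",                           "g",
  "mufa_g",               "Total Monounsaturated Fat",           "g",
  "pufa_g",               "Total Polyunsaturated Fat",           "g",
  "sat_fat_g",            "Total Saturated Fat",                 "g",
  "sugars_g",             "Total Sugars",                        "g",
  "trans_fat_g",          "Trans Fat",                           "g",
  "vit_a_rae_mcg",        "Vitamin A RAE",                       "mcg",
  "vit_b12_mcg",          "Vitamin B12",                         "mcg",
  "vit_b6_mg",            "Vitamin B6",                          "mg",
  "vit_c_mg",             "Vitamin C",                           "mg",
  "vit_d_mcg",            "Vitamin D (D2+D3)",                   "mcg",
  "vit_e_mg",             "Vitamin E, as alpha-tocopherol",      "mg",
  "vit_k_mcg",            "Vitamin K",                           "mcg",
  "zinc_mg",              "Zinc",                                "mg"
)

#' Nutrient keys tracked by the package
#'
#' Returns the canonical set of 37 nutrient column names used throughout the
#' package: every recall dataset carries one nonnegative column per key, and a
#' missing key is a validation error (never silently zero). Selenium and
#' vitamin K are carried in micrograms, the physiologically sensible unit for
#' their typical daily amounts.
#'
#' @return Character vector of 37 column names, e.g. `"calcium_mg"`,
#'   `"choline_mg"`, `"energy_kcal"`.
#' @seealso [nutrient_info()] for display labels and units.
#' @export
#' @examples
#' length(nutrient_keys())
nutrient_keys <- function() .NUTRIENTS$key

#' Nutrient labels and units
#'
#' @return A tibble with columns `key`, `label`, `unit` for the 37 tracked
#'   nutrients.
#' @export
nutrient_info <- function() .NUTRIENTS

# kcal per gram used when deriving energy from macronutrients (Atwater).
.ATWATER <- c(carbohydrate_g = 4, protein_g = 4, total_fat_g = 9)
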