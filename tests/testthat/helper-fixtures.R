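# Programmatic fixtures: small recall tables built item by item.

zero_nutrients <- function() {
  stats::setNames(as.list(rep(0, length(nutrient_keys()))), nutrient_keys())
}

# One recall item row. Nutrient overrides via `...` (e.g. choline_mg = 100).
make_item <- function(person_id = "P1", age_years = 10L, sex = "male",
                      day1_weight = 1, stratum_id = "ST1", psu_id = "ST1_P1",
                      day_index = 1L, occasion_code = "breakfast",
                      food_code = "f1", category = "other", amount = 1,
                      milk_fat_level = NA_character_, milk_flavored = NA, ...) {
  nut <- utils::modifyList(zero_nutrients(), list(...))
  if (category == "milk" && is.na(milk_fat_level)) {
    milk_fat_level <- "skim"
    milk_flavored <- FALSE
  }
  dplyr::bind_cols(
    tibble::tibble(
      person_id = person_id, age_years = as.integer(age_years), sex = sex,
      day1_weight = day1_weight, stratum_id = stratum_id, psu_id = psu_id,
      day_index = as.integer(day_index), occasion_code = occasion_code,
      food_code = food_code, category = category, amount = amount,
      milk_fat_level = milk_fat_level, milk_flavored = milk_flavored
    ),
    tibble::as_tibble(nut)
  )
}

make_recalls <- function(...) dplyr::bind_rows(...)

# A breakfast of given milk/fruit/grain composition for one person-day.
make_breakfast <- function(person_id = "P1", age_years = 10L, day_index = 1L,
                           milk_oz = 8, milk_fat = "skim", milk_flavored = FALSE,
                           fruit_oz = 0.6, grain_oz = 1.0, ...) {
  make_recalls(
    make_item(person_id, age_years, day_index = day_index, food_code = "milk1",
              category = "milk", amount = milk_oz, milk_fat_level = milk_fat,
              milk_flavored = milk_flavored, ...),
    make_item(person_id, age_years, day_index = day_index, food_code = "fv1",
              category = "fruit_vegetable", amount = fruit_oz, ...),
    make_item(person_id, age_years, day_index = day_index, food_code = "gr1",
              category = "grain", amount = grain_oz, ...)
  )
}

# Independent re-implementation of the CACFP rule table, hand-coded from the
# age-band minimums, used as the enumeration oracle.
cacfp_oracle <- function(age, milk_fat, milk_flavored, milk_oz, fruit_oz, grain_oz) {
  milk_type_ok <-
    if (age == 1) milk_fat == "whole" && !milk_flavored
    else if (milk_fat == "lowfat_1pct") !milk_flavored
    else if (milk_fat == "skim") (!milk_flavored) || age >= 6
    else FALSE
  min_milk <- if (age <= 2) 4 else if (age <= 5) 6 else 8
  min_fruit <- if (age <= 2) 0.25 else 0.5
  min_grain <- if (age <= 5) 0.5 else 1.0
  milk_type_ok && milk_oz >= min_milk && fruit_oz >= min_fruit &&
    grain_oz >= min_grain
}
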