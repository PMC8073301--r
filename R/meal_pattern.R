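# Breakfast classification: habitual egg consumption at breakfast, and
# CACFP component compliance under the USDA age-band rule table.

#' CACFP breakfast rule table
#'
#' Loads the packaged (or a user-supplied) YAML rule table giving, per age
#' band, the minimum fluid-milk ounces with allowed milk fat level/flavoring,
#' and the minimum fruit/vegetable and grain ounce equivalents.
#'
#' @param path Optional path to an alternative YAML rule file.
#' @return A list of class `cacfp_rules` with elements `milk`,
#'   `fruit_vegetable`, `grain`.
#' @export
cacfp_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cacfp_rules.yaml", package = "dietshift")
  rules <- yaml::read_yaml(path)
  structure(rules, class = "cacfp_rules")
}

.band_for <- function(bands, age) {
  for (b in bands) if (age >= b$age_min && age <= b$age_max) return(b)
  abort_ds(sprintf("no rule band covers age %d", age), "dietshift_config")
}

# Is each milk item row an allowed milk for its consumer's age band?
.milk_allowed <- function(age, fat_level, flavored, rules) {
  ok <- rep(FALSE, length(age))
  for (band in rules$milk) {
    in_band <- age >= band$age_min & age <= band$age_max
    for (a in band$allowed) {
      ok <- ok | (in_band & fat_level == a$fat_level & flavored == a$flavored)
    }
  }
  ok
}

.min_lookup <- function(bands, ages, field) {
  vapply(ages, function(a) as.numeric(.band_for(bands, a)[[field]]), numeric(1))
}

#' Classify CACFP compliance of each person-day breakfast
#'
#' A breakfast is CACFP compliant when its milk, fruit/vegetable, and grain
#' components all meet or exceed the age-band minimums, with milk counted
#' only over items whose fat level and flavoring are allowed for the band.
#' Amounts sum across items of the same category within the breakfast. A day
#' with no breakfast occasion is non-compliant.
#'
#' @param recalls A validated recall tibble.
#' @param rules A [cacfp_rules()] table.
#' @return Tibble `person_id`, `day_index`, `cacfp_compliant`.
#' @export
classify_cacfp <- function(recalls, rules = cacfp_rules()) {
  recalls <- tibble::as_tibble(recalls)
  grid <- dplyr::distinct(recalls, .data$person_id, .data$day_index, .data$age_years)
  bf <- recalls[recalls$occasion_code == "breakfast", , drop = FALSE]
  bf$milk_ok <- bf$category == "milk" &
    .milk_allowed(bf$age_years, bf$milk_fat_level, bf$milk_flavored, rules)
  comp <- bf |>
    dplyr::group_by(.data$person_id, .data$day_index) |>
    dplyr::summarise(
      milk_amt = sum(.data$amount[.data$milk_ok]),
      fv_amt = sum(.data$amount[.data$category == "fruit_vegetable"]),
      gr_amt = sum(.data$amount[.data$category == "grain"]),
      .groups = "drop"
    )
  out <- dplyr::left_join(grid, comp, by = c("person_id", "day_index"))
  out$cacfp_compliant <-
    !is.na(out$milk_amt) &
    out$milk_amt >= .min_lookup(rules$milk, out$age_years, "min_fl_oz") &
    out$fv_amt >= .min_lookup(rules$fruit_vegetable, out$age_years, "min_oz_eq") &
    out$gr_amt >= .min_lookup(rules$grain, out$age_years, "min_oz_eq")
  out |>
    dplyr::select("person_id", "day_index", "cacfp_compliant") |>
    dplyr::arrange(.data$person_id, .data$day_index)
}

#' Detect eggs at breakfast per person-day
#'
#' True exactly when the day's breakfast occasion contains at least one item
#' of category `egg` (whole, boiled, or poached eggs). Egg substitutes,
#' other poultry eggs, and egg-containing mixed dishes never count.
#'
#' @param recalls A validated recall tibble.
#' @return Tibble `person_id`, `day_index`, `egg_at_breakfast`.
#' @export
detect_egg_at_breakfast <- function(recalls) {
  recalls <- tibble::as_tibble(recalls)
  grid <- dplyr::distinct(recalls, .data$person_id, .data$day_index)
  hits <- recalls |>
    dplyr::filter(.data$occasion_code == "breakfast", .data$category == "egg") |>
    dplyr::distinct(.data$person_id, .data$day_index) |>
    dplyr::mutate(egg_at_breakfast = TRUE)
  dplyr::left_join(grid, hits, by = c("person_id", "day_index")) |>
    dplyr::mutate(egg_at_breakfast = !is.na(.data$egg_at_breakfast)) |>
    dplyr::arrange(.data$person_id, .data$day_index)
}

#' Person-level breakfast status
#'
#' Aggregates day-level classifications to the person level for scenario
#' eligibility: a person is an egg-at-breakfast consumer if eggs appear at
#' breakfast on ANY reliable recall day (a conservative reading of "typically
#' consumes"); CACFP compliance and breakfast presence are judged on day 1
#' only, matching a day-1-weighted analysis.
#'
#' @param recalls A validated recall tibble.
#' @param rules A [cacfp_rules()] table.
#' @return Tibble `person_id`, `has_breakfast`, `egg_at_breakfast`,
#'   `cacfp_compliant`.
#' @export
person_status <- function(recalls, rules = cacfp_rules()) {
  recalls <- tibble::as_tibble(recalls)
  if (nrow(recalls) == 0) abort_ds("empty recall collection", "dietshift_validation")
  egg <- detect_egg_at_breakfast(recalls) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(egg_at_breakfast = any(.data$egg_at_breakfast), .groups = "drop")
  day1 <- recalls[recalls$day_index == 1L, , drop = FALSE]
  hb <- day1 |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(has_breakfast = any(.data$occasion_code == "breakfast"),
                     .groups = "drop")
  cc <- classify_cacfp(day1, rules) |>
    dplyr::select("person_id", cacfp_compliant = "cacfp_compliant")
  persons <- recall_persons(recalls)["person_id"]
  persons |>
    dplyr::left_join(egg, by = "person_id") |>
    dplyr::left_join(hb, by = "person_id") |>
    dplyr::left_join(cc, by = "person_id") |>
    dplyr::mutate(
      has_breakfast = tidyr::replace_na(.data$has_breakfast, FALSE),
      cacfp_compliant = tidyr::replace_na(.data$cacfp_compliant, FALSE)
    ) |>
    dplyr::select("person_id", "has_breakfast", "egg_at_breakfast", "cacfp_compliant")
}
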