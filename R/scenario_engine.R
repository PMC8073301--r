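# Scenario engine: add egg nutrient-profile equivalents to eligible
# breakfasts. Scenarios S1/S2 target persons with breakfast but no habitual
# eggs at breakfast; S3/S4 target persons whose day-1 breakfast is CACFP
# compliant. S0 is the untouched baseline.

.SCENARIOS <- list(
  S0_baseline    = list(n_eggs = 0L, eligibility = "all"),
  S1_plus1       = list(n_eggs = 1L, eligibility = "egg_free_breakfast"),
  S2_plus2       = list(n_eggs = 2L, eligibility = "egg_free_breakfast"),
  S3_cacfp_plus1 = list(n_eggs = 1L, eligibility = "cacfp_compliant_breakfast"),
  S4_cacfp_plus2 = list(n_eggs = 2L, eligibility = "cacfp_compliant_breakfast")
)

#' Scenario specification
#'
#' @param id One of `"S0_baseline"`, `"S1_plus1"`, `"S2_plus2"`,
#'   `"S3_cacfp_plus1"`, `"S4_cacfp_plus2"` (short aliases `"S0"`..`"S4"`
#'   accepted).
#' @return A list of class `scenario_spec` with `id`, `n_eggs`, `eligibility`.
#' @export
scenario_spec <- function(id) {
  full <- names(.SCENARIOS)
  if (id %in% paste0("S", 0:4)) id <- full[match(id, substr(full, 1, 2))]
  if (!id %in% full) {
    abort_ds(paste0("unknown scenario id: ", id), "dietshift_config")
  }
  structure(c(list(id = id), .SCENARIOS[[id]]), class = "scenario_spec")
}

#' Egg nutrient profile
#'
#' Loads the packaged per-egg nutrient profile (one large 50 g egg = 1 oz eq)
#' or a user-supplied YAML override. The packaged profile carries 147 mg
#' total choline and 250 mcg lutein + zeaxanthin per egg; the remaining
#' components come from a standard whole-egg composition reference.
#'
#' @param path Optional path to an alternative YAML profile.
#' @return Named numeric vector over all 37 nutrient keys.
#' @export
egg_profile <- function(path = NULL) {
  path <- path %||% system.file("extdata", "egg_profile.yaml", package = "dietshift")
  prof <- unlist(yaml::read_yaml(path)$nutrients)
  missing <- setdiff(nutrient_keys(), names(prof))
  if (length(missing) > 0) {
    abort_ds(paste0("egg profile missing nutrient(s): ",
                    paste(missing, collapse = ", ")), "dietshift_config")
  }
  if (any(prof < 0)) abort_ds("egg profile components must be >= 0", "dietshift_config")
  prof[nutrient_keys()]
}

#' Apply a modeling scenario
#'
#' For every eligible person, each recall day that has a breakfast occasion
#' gains one synthetic egg item whose nutrient vector is `n_eggs` times the
#' profile (tagged with `food_code = "egg_synthetic"` so modeled intake can
#' be separated from observed intake). Ineligible persons, days without a
#' breakfast, and non-breakfast occasions are untouched; the input is not
#' mutated. `S0_baseline` returns the input unchanged.
#'
#' @param recalls A validated recall tibble.
#' @param spec A [scenario_spec()] (or scenario id string).
#' @param status Per-person [person_status()] table.
#' @param profile Per-egg nutrient vector, see [egg_profile()].
#' @return A validated recall tibble with synthetic egg items appended.
#' @export
apply_scenario <- function(recalls, spec, status, profile = egg_profile()) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  recalls <- tibble::as_tibble(recalls)
  if (spec$n_eggs == 0L) return(recalls)
  missing <- setdiff(unique(recalls$person_id), status$person_id)
  if (length(missing) > 0) {
    abort_ds("status does not cover every person in the collection",
             "dietshift_validation")
  }
  eligible <- switch(spec$eligibility,
    all = status$person_id,
    egg_free_breakfast =
      status$person_id[status$has_breakfast & !status$egg_at_breakfast],
    cacfp_compliant_breakfast = status$person_id[status$cacfp_compliant]
  )
  bf_days <- recalls |>
    dplyr::filter(.data$occasion_code == "breakfast",
                  .data$person_id %in% eligible) |>
    dplyr::distinct(.data$person_id, .data$day_index, .data$age_years,
                    .data$sex, .data$day1_weight, .data$stratum_id, .data$psu_id)
  if (nrow(bf_days) == 0) return(recalls)
  egg_rows <- dplyr::bind_cols(
    bf_days,
    tibble::tibble(
      occasion_code = "breakfast", food_code = "egg_synthetic",
      category = "egg", amount = as.numeric(spec$n_eggs),
      milk_fat_level = NA_character_, milk_flavored = NA
    ),
    tibble::as_tibble(as.data.frame(
      matrix(rep(profile * spec$n_eggs, nrow(bf_days)), nrow = nrow(bf_days),
             byrow = TRUE, dimnames = list(NULL, names(profile)))
    ))
  )[, recall_cols()]
  out <- dplyr::bind_rows(recalls, egg_rows) |>
    dplyr::arrange(.data$person_id, .data$day_index, .data$occasion_code,
                   .data$food_code)
  validate_recalls(out)
  out
}

#' Per-person-day nutrient deltas between two collections
#'
#' Componentwise whole-day difference `after - before` for every person-day.
#' Both collections must cover the same person-day keys.
#'
#' @param before,after Validated recall tibbles.
#' @return Tibble `person_id`, `day_index`, plus the 37 nutrient difference
#'   columns.
#' @export
scenario_delta <- function(before, after) {
  nk <- nutrient_keys()
  a <- sum_nutrients(before, "whole_day")
  b <- sum_nutrients(after, "whole_day")
  key_a <- paste(a$person_id, a$day_index)
  key_b <- paste(b$person_id, b$day_index)
  if (!identical(sort(key_a), sort(key_b))) {
    abort_ds("person-day keys differ between collections", "dietshift_validation")
  }
  b <- b[match(key_a, key_b), , drop = FALSE]
  out <- a[, c("person_id", "day_index")]
  for (k in nk) out[[k]] <- b[[k]] - a[[k]]
  out
}
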