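# Cut-point adequacy analysis: percent of the usual-intake distribution
# below an EAR / above an AI (person-matched by age band and sex), fixed
# cutoffs for sodium and saturated-fat energy share, normal 95% CIs,
# CI-overlap significance calls, and >=10% / >=20% change flags.

.SODIUM_CUTOFF_MG <- 2300
.SATFAT_ENERGY_CUTOFF <- 0.10

#' Dietary Reference Intake table
#'
#' Loads the packaged (or user-supplied) YAML table of EAR/AI reference
#' values by nutrient, sex, and age band.
#'
#' @param path Optional path to an alternative YAML file.
#' @return Tibble with columns `nutrient`, `reference_type`, `sex`
#'   (`male`/`female`/`both`), `age_min`, `age_max`, `value`.
#' @export
dri_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dri_reference.yaml", package = "dietshift")
  raw <- yaml::read_yaml(path)$references
  dplyr::bind_rows(lapply(raw, function(r) {
    dplyr::bind_rows(lapply(r$bands, tibble::as_tibble)) |>
      dplyr::mutate(nutrient = r$nutrient, reference_type = r$reference_type,
                    .before = 1)
  }))
}

#' Look up person-matched DRI values
#'
#' @param dri A [dri_table()].
#' @param nutrient Nutrient key.
#' @param ages,sexes Equal-length vectors of ages (years) and sexes.
#' @return Numeric vector of reference values; errors (class
#'   `dietshift_config`) if any (age, sex) is uncovered.
#' @export
dri_lookup <- function(dri, nutrient, ages, sexes) {
  rows <- dri[dri$nutrient == nutrient, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort_ds(paste0("no DRI entry for nutrient: ", nutrient), "dietshift_config")
  }
  out <- rep(NA_real_, length(ages))
  for (i in seq_len(nrow(rows))) {
    hit <- ages >= rows$age_min[i] & ages <= rows$age_max[i] &
      (rows$sex[i] == "both" | sexes == rows$sex[i])
    out[hit] <- rows$value[i]
  }
  if (anyNA(out)) {
    j <- which(is.na(out))[1]
    abort_ds(sprintf("no DRI band for %s covers age %s sex %s",
                     nutrient, ages[j], sexes[j]), "dietshift_config")
  }
  out
}

.cutpoint_pct <- function(usual, dri, direction) {
  stopifnot(inherits(usual, "usual_intake_summary"))
  smp <- usual$sample
  ref <- dri_lookup(dri, usual$nutrient, smp$age_years, smp$sex)
  hit <- if (direction == "below") smp$usual < ref else smp$usual > ref
  100 * weighted_mean(as.numeric(hit), smp$weight)
}

#' Percent of the population below the EAR
#'
#' The cut-point estimate of the prevalence of inadequacy: the
#' survey-weighted fraction of the usual-intake sample falling below each
#' pseudo-person's age/sex-matched Estimated Average Requirement, times 100.
#'
#' @param usual A `usual_intake_summary` with its `nutrient` set.
#' @param dri A [dri_table()] with an EAR entry for the nutrient.
#' @return List with `nutrient`, `metric`, `estimate` (percent).
#' @export
pct_below_ear <- function(usual, dri = dri_table()) {
  rt <- unique(dri$reference_type[dri$nutrient == usual$nutrient])
  if (!"EAR" %in% rt) {
    abort_ds(paste0("no EAR reference for ", usual$nutrient), "dietshift_config")
  }
  list(nutrient = usual$nutrient, metric = "pct_below_EAR",
       estimate = .cutpoint_pct(usual, dri[dri$reference_type == "EAR", ], "below"))
}

#' Percent of the population above the AI
#'
#' @inheritParams pct_below_ear
#' @return List with `nutrient`, `metric`, `estimate` (percent).
#' @export
pct_above_ai <- function(usual, dri = dri_table()) {
  rt <- unique(dri$reference_type[dri$nutrient == usual$nutrient])
  if (!"AI" %in% rt) {
    abort_ds(paste0("no AI reference for ", usual$nutrient), "dietshift_config")
  }
  list(nutrient = usual$nutrient, metric = "pct_above_AI",
       estimate = .cutpoint_pct(usual, dri[dri$reference_type == "AI", ], "above"))
}

#' Percent of the population above a fixed dietary cutoff
#'
#' Two cutoffs are supported: usual sodium above 2300 mg/day, and usual
#' saturated-fat energy share above 10% of calories. The saturated-fat share
#' is a ratio of usual intakes, `9 * usual_satfat / usual_energy`, paired by
#' Monte-Carlo pseudo-person (estimate both summaries with the same seed so
#' pseudo-persons align) -- a documented approximation, not a bivariate
#' measurement-error model.
#'
#' @param usual Usual-intake summary of the numerator nutrient (`sodium_mg`
#'   or `sat_fat_g`).
#' @param cutoff `"sodium"` or `"sat_fat_energy"`.
#' @param usual_energy Usual-intake summary of `energy_kcal`; required for
#'   the saturated-fat cutoff.
#' @return List with `nutrient`, `metric`, `estimate` (percent).
#' @export
pct_above_cutoff <- function(usual, cutoff = c("sodium", "sat_fat_energy"),
                             usual_energy = NULL) {
  cutoff <- match.arg(cutoff)
  smp <- usual$sample
  if (cutoff == "sodium") {
    hit <- smp$usual > .SODIUM_CUTOFF_MG
  } else {
    if (is.null(usual_energy)) {
      abort_ds("usual_energy is required for the saturated-fat cutoff",
               "dietshift_config")
    }
    en <- usual_energy$sample$usual
    stopifnot(length(en) == nrow(smp))
    if (any(en <= 0)) abort_ds("usual energy must be positive", "dietshift_validation")
    hit <- 9 * smp$usual / en > .SATFAT_ENERGY_CUTOFF
  }
  list(nutrient = usual$nutrient,
       metric = paste0("pct_above_", cutoff),
       estimate = 100 * weighted_mean(as.numeric(hit), smp$weight))
}

#' Normal 95% confidence interval for a percentage
#'
#' `estimate +/- 1.96 * se`, truncated to `[0, 100]` and rounded to one
#' decimal for reporting.
#'
#' @param estimate_pct Point estimate in percent.
#' @param se Standard error (>= 0) in percentage points.
#' @return Named numeric `c(lcl, ucl)`.
#' @export
normal_ci <- function(estimate_pct, se) {
  if (is.na(se) || se < 0) abort_ds("se must be >= 0", "dietshift_validation")
  lo <- max(0, estimate_pct - 1.96 * se)
  hi <- min(100, estimate_pct + 1.96 * se)
  c(lcl = round(lo, 1), ucl = round(hi, 1))
}

#' Non-overlap significance call for two confidence intervals
#'
#' TRUE exactly when the intervals are disjoint; intervals that share an
#' endpoint overlap and give FALSE.
#'
#' @param baseline_ci,scenario_ci Length-2 numeric `(lcl, ucl)`.
#' @return Logical scalar.
#' @export
ci_overlap_call <- function(baseline_ci, scenario_ci) {
  stopifnot(length(baseline_ci) == 2, length(scenario_ci) == 2,
            baseline_ci[1] <= baseline_ci[2], scenario_ci[1] <= scenario_ci[2])
  unname(baseline_ci[2] < scenario_ci[1] || scenario_ci[2] < baseline_ci[1])
}

#' Percent-change flag versus baseline
#'
#' `"ge20"` when the relative change `(scenario - baseline) / baseline` is at
#' least +20%, `"ge10"` when at least +10%, else `"none"`. Comparisons must
#' be made on unrounded means; rounding for display happens afterwards.
#'
#' @param baseline_mean Positive baseline mean.
#' @param scenario_mean Scenario mean.
#' @return One of `"none"`, `"ge10"`, `"ge20"`.
#' @export
change_flag <- function(baseline_mean, scenario_mean) {
  if (is.na(baseline_mean) || baseline_mean <= 0) {
    abort_ds("baseline mean must be positive", "dietshift_validation")
  }
  rel <- (scenario_mean - baseline_mean) / baseline_mean
  if (rel >= 0.20) "ge20" else if (rel >= 0.10) "ge10" else "none"
}
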