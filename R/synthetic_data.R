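# Synthetic multi-day recall generator. Emulates the statistical structure
# the downstream estimators assume: lognormal daily intakes with additive
# person and day effects on the log scale, breakfast occasions carrying
# milk / fruit-vegetable / grain (and sometimes egg) items, survey design
# columns (stratum, PSU, day-1 weight). It does not emulate survey
# oversampling or nonresponse; weights default to uniform.

#' Default per-nutrient generator parameters
#'
#' One row per drawn nutrient: log-scale mean `mu_log` and between-/within-
#' person standard deviations. `mu_log` is calibrated so that the implied
#' lognormal population mean `exp(mu_log + (sb^2 + sw^2)/2)` sits at a
#' realistic daily intake for US children aged 1--18 (within about 20% of
#' published national baseline means). Energy is not drawn: it is derived
#' from the macronutrients at 4/4/9 kcal per g of carbohydrate/protein/fat,
#' so that the saturated-fat percent-of-energy cutoff is meaningful.
#'
#' @param sigma_between,sigma_within Log-scale SDs applied to every nutrient.
#' @return Tibble with columns `nutrient`, `mu_log`, `sigma_between`,
#'   `sigma_within` (36 rows; all keys except `energy_kcal`).
#' @export
default_nutrient_params <- function(sigma_between = 0.3, sigma_within = 0.5) {
  target_means <- c(
    calcium_mg = 1020, carbohydrate_g = 244, cholesterol_mg = 214,
    fiber_g = 13.9, folate_dfe_mcg = 500, iron_mg = 13.7,
    lutein_zeaxanthin_mcg = 770, magnesium_mg = 231, niacin_mg = 20.8,
    pantothenic_acid_mg = 28.3, pfa_18_2_g = 13.7, pfa_18_3_g = 1.3,
    pfa_20_5_g = 0.01, pfa_22_6_g = 0.02, phosphorus_mg = 1250,
    potassium_mg = 2150, protein_g = 66.8, riboflavin_mg = 1.9,
    selenium_mcg = 94, sodium_mg = 2920, thiamin_mg = 1.5,
    choline_mg = 248, total_fat_g = 69.8, mufa_g = 23.6, pufa_g = 15.4,
    sat_fat_g = 24.6, sugars_g = 115, trans_fat_g = 1.9,
    vit_a_rae_mcg = 594, vit_b12_mcg = 4.7, vit_b6_mg = 1.7,
    vit_c_mg = 74, vit_d_mcg = 5.7, vit_e_mg = 6.9, vit_k_mcg = 64.8,
    zinc_mg = 9.8
  )
  tibble::tibble(
    nutrient = names(target_means),
    mu_log = log(unname(target_means)) - (sigma_between^2 + sigma_within^2) / 2,
    sigma_between = sigma_between,
    sigma_within = sigma_within
  )
}

#' Generator configuration
#'
#' Assembles and validates the configuration for [generate_recalls()].
#' Defaults describe the study population the package models: children aged
#' 1--18 with two recall days each, roughly 15% of person-days skipping
#' breakfast, about 20% of children typically consuming eggs at breakfast,
#' and about 1.7% of breakfasts meeting the CACFP component rules (the share
#' observed in national survey data for this age range).
#'
#' @param n_persons Number of persons (each gets 2 recall days).
#' @param seed Integer RNG seed; identical configs give identical output.
#' @param age_range Inclusive integer bounds on age in years, within 1--18.
#' @param nutrient_params Tibble as returned by [default_nutrient_params()].
#' @param breakfast_skip_prob Per-day probability of no breakfast occasion.
#' @param egg_at_breakfast_prob Per-person probability of being a habitual
#'   egg-at-breakfast consumer (an egg item then appears on every breakfast).
#' @param cacfp_compliant_target Per-breakfast probability of drawing a
#'   CACFP-compliant component set.
#' @param breakfast_share Fraction of daily nutrients allocated to the
#'   breakfast occasion when one is present.
#' @param weight_distribution `"uniform"` (all weights 1) or `"lognormal"`.
#' @param weight_log_sd Log-scale SD of lognormal weights.
#' @param n_strata,psus_per_stratum Survey design layout.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_persons = 500,
                             seed = 1L,
                             age_range = c(1L, 18L),
                             nutrient_params = default_nutrient_params(),
                             breakfast_skip_prob = 0.15,
                             egg_at_breakfast_prob = 0.20,
                             cacfp_compliant_target = 0.017,
                             breakfast_share = 0.22,
                             weight_distribution = c("uniform", "lognormal"),
                             weight_log_sd = 0.5,
                             n_strata = 4L,
                             psus_per_stratum = 3L) {
  weight_distribution <- match.arg(weight_distribution)
  probs <- c(breakfast_skip_prob, egg_at_breakfast_prob, cacfp_compliant_target)
  if (any(probs < 0 | probs > 1)) {
    abort_ds("probabilities must lie in [0, 1]", "dietshift_config")
  }
  if (n_persons < 0 || n_strata < 1 || psus_per_stratum < 1) {
    abort_ds("n_persons must be >= 0 and design counts positive", "dietshift_config")
  }
  if (age_range[1] < 1 || age_range[2] > 18 || age_range[1] > age_range[2]) {
    abort_ds("age_range must lie within [1, 18]", "dietshift_config")
  }
  stopifnot(all(c("nutrient", "mu_log", "sigma_between", "sigma_within") %in%
                  names(nutrient_params)))
  if (any(nutrient_params$sigma_between < 0) || any(nutrient_params$sigma_within < 0)) {
    abort_ds("variance components must be >= 0", "dietshift_config")
  }
  structure(
    list(
      n_persons = as.integer(n_persons), seed = as.integer(seed),
      age_range = as.integer(age_range), nutrient_params = nutrient_params,
      breakfast_skip_prob = breakfast_skip_prob,
      egg_at_breakfast_prob = egg_at_breakfast_prob,
      cacfp_compliant_target = cacfp_compliant_target,
      breakfast_share = breakfast_share,
      weight_distribution = weight_distribution,
      weight_log_sd = weight_log_sd,
      n_strata = as.integer(n_strata),
      psus_per_stratum = as.integer(psus_per_stratum)
    ),
    class = "generator_config"
  )
}

# Nutrient split of a breakfast across its items. Eggs, when present as an
# observed (habitual) item, take a share too; weights renormalize over the
# items actually present.
.BF_ITEM_SHARE <- c(milk = 0.35, fruit_vegetable = 0.25, grain = 0.30, egg = 0.10)

#' Generate a synthetic recall dataset
#'
#' Daily intake of nutrient k for person p on day d is
#' `exp(mu_log_k + b_pk + e_pdk)` with `b_pk ~ N(0, sigma_between_k^2)` and
#' `e_pdk ~ N(0, sigma_within_k^2)`; energy is derived from the day's
#' macronutrients. Each person contributes two recall days. When a breakfast
#' occasion is present it receives a fixed share of the day's nutrients,
#' split across milk, fruit/vegetable, grain and (for habitual egg
#' consumers) egg items; CACFP component amounts (milk fl oz, fruit and
#' grain oz eq) are drawn so that each breakfast is compliant with
#' probability `cacfp_compliant_target`.
#'
#' @param config A [generator_config()].
#' @return A validated recall tibble (empty, with the full column set, when
#'   `n_persons = 0`).
#' @export
generate_recalls <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  out <- withr::with_seed(config$seed, .generate_impl(config))
  validate_recalls(out)
  out
}

.empty_recalls <- function() {
  cols <- c(
    list(person_id = character(), age_years = integer(), sex = character(),
         day1_weight = double(), stratum_id = character(), psu_id = character(),
         day_index = integer(), occasion_code = character(),
         food_code = character(), category = character(), amount = double(),
         milk_fat_level = character(), milk_flavored = logical()),
    stats::setNames(rep(list(double()), length(nutrient_keys())), nutrient_keys())
  )
  tibble::as_tibble(cols)
}

.generate_impl <- function(config) {
  n <- config$n_persons
  if (n == 0) return(.empty_recalls())
  np <- config$nutrient_params
  K <- nrow(np)

  persons <- tibble::tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    age_years = {
      ages <- seq.int(config$age_range[1], config$age_range[2])
      ages[sample.int(length(ages), n, replace = TRUE)]
    },
    sex = sample(c("male", "female"), n, replace = TRUE),
    day1_weight = switch(config$weight_distribution,
      uniform = rep(1, n),
      lognormal = exp(stats::rnorm(n, 0, config$weight_log_sd))
    ),
    stratum_id = sprintf("ST%02d", sample.int(config$n_strata, n, replace = TRUE)),
    egg_consumer = stats::runif(n) < config$egg_at_breakfast_prob
  )
  persons$psu_id <- sprintf("%s_PSU%02d", persons$stratum_id,
                            sample.int(config$psus_per_stratum, n, replace = TRUE))

  # Person-day log-scale effects; rows = person-days (day 1 block then day 2).
  b <- matrix(stats::rnorm(n * K), n, K) %*% diag(np$sigma_between, K)
  days <- tidyr::expand_grid(idx = seq_len(n), day_index = 1:2)
  e <- matrix(stats::rnorm(nrow(days) * K), nrow(days), K) %*% diag(np$sigma_within, K)
  logD <- matrix(np$mu_log, nrow(days), K, byrow = TRUE) + b[days$idx, , drop = FALSE] + e
  D <- exp(logD)
  colnames(D) <- np$nutrient
  energy <- as.vector(D[, names(.ATWATER), drop = FALSE] %*% .ATWATER)
  D <- cbind(D, energy_kcal = energy)
  D <- D[, nutrient_keys(), drop = FALSE]

  days$has_breakfast <- stats::runif(nrow(days)) >= config$breakfast_skip_prob
  days$age <- persons$age_years[days$idx]
  days$egg <- persons$egg_consumer[days$idx]

  # CACFP component draws for breakfast days.
  bf <- days$has_breakfast
  nbf <- sum(bf)
  comp <- rep(NA, nrow(days))
  comp[bf] <- stats::runif(nbf) < config$cacfp_compliant_target
  age_bf <- days$age
  min_milk <- ifelse(age_bf <= 2, 4, ifelse(age_bf <= 5, 6, 8))
  min_fv <- ifelse(age_bf <= 2, 0.25, 0.5)
  min_gr <- ifelse(age_bf <= 5, 0.5, 1.0)
  milk_type <- ifelse(age_bf == 1, "whole",
                      ifelse(stats::runif(nrow(days)) < 0.5, "skim", "lowfat_1pct"))
  milk_flav <- age_bf >= 6 & milk_type == "skim" & stats::runif(nrow(days)) < 0.2
  milk_oz <- min_milk * (1 + 0.5 * stats::runif(nrow(days)))
  fv_oz <- min_fv * (1 + stats::runif(nrow(days)))
  gr_oz <- min_gr * (1 + stats::runif(nrow(days)))
  # Break exactly one component on non-compliant breakfasts.
  breaker <- sample(c("milk_type", "milk_low", "fruit_low", "grain_low"),
                    nrow(days), replace = TRUE)
  nc <- bf & !comp
  milk_type[nc & breaker == "milk_type"] <- "reduced_2pct"
  short <- function(m) m * (0.2 + 0.6 * stats::runif(length(m)))
  i <- nc & breaker == "milk_low"; milk_oz[i] <- short(min_milk[i])
  i <- nc & breaker == "fruit_low"; fv_oz[i] <- short(min_fv[i])
  i <- nc & breaker == "grain_low"; gr_oz[i] <- short(min_gr[i])
  milk_flav[nc & breaker == "milk_type"] <- FALSE

  person_cols <- function(ii) {
    tibble::tibble(
      person_id = persons$person_id[ii], age_years = persons$age_years[ii],
      sex = persons$sex[ii], day1_weight = persons$day1_weight[ii],
      stratum_id = persons$stratum_id[ii], psu_id = persons$psu_id[ii]
    )
  }
  nutri_tbl <- function(mat) tibble::as_tibble(as.data.frame(mat))

  s <- config$breakfast_share
  make_bf_item <- function(sel, category, food_code, amount, fat = NA_character_,
                           flav = NA) {
    if (!any(sel)) return(NULL)
    share <- .BF_ITEM_SHARE[[if (category %in% names(.BF_ITEM_SHARE)) category else "egg"]]
    denom <- ifelse(days$egg[sel], sum(.BF_ITEM_SHARE),
                    sum(.BF_ITEM_SHARE[c("milk", "fruit_vegetable", "grain")]))
    frac <- s * share / denom
    dplyr::bind_cols(
      person_cols(days$idx[sel]),
      tibble::tibble(
        day_index = as.integer(days$day_index[sel]),
        occasion_code = "breakfast", food_code = food_code,
        category = category, amount = amount[sel],
        milk_fat_level = if (length(fat) > 1) fat[sel] else fat,
        milk_flavored = if (length(flav) > 1) flav[sel] else flav
      ),
      nutri_tbl(D[sel, , drop = FALSE] * frac)
    )
  }

  egg_bf <- bf & days$egg
  rows <- list(
    make_bf_item(bf, "milk", "milk_obs", milk_oz, fat = milk_type, flav = milk_flav),
    make_bf_item(bf, "fruit_vegetable", "fv_obs", fv_oz),
    make_bf_item(bf, "grain", "grain_obs", gr_oz),
    make_bf_item(egg_bf, "egg", "egg_obs", rep(1, nrow(days)))
  )

  # Remainder of the day (everything when breakfast is skipped).
  bf_frac <- ifelse(bf, ifelse(days$egg, s, s), 0)
  rest <- dplyr::bind_cols(
    person_cols(days$idx),
    tibble::tibble(
      day_index = as.integer(days$day_index),
      occasion_code = "other", food_code = "other_obs", category = "other",
      amount = 1, milk_fat_level = NA_character_, milk_flavored = NA
    ),
    nutri_tbl(D * (1 - bf_frac))
  )
  out <- dplyr::bind_rows(c(rows, list(rest)))
  out |>
    dplyr::arrange(.data$person_id, .data$day_index, .data$occasion_code,
                   .data$food_code) |>
    dplyr::select(dplyr::all_of(recall_cols()))
}
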