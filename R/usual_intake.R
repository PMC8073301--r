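# Usual-intake estimation from repeated 24-h recalls: a one-part
# measurement-error model in the style of the NCI method. Daily intakes are
# carried to approximate normality by a shifted Box-Cox transform; a
# random-effects decomposition separates between-person from within-person
# (day-to-day) variance; the usual-intake distribution is recovered by
# simulating person effects and back-transforming with Gauss-Hermite
# quadrature over the within-person error, which supplies the bias
# correction a naive plug-in back-transform lacks.

.DEFAULT_LAMBDA_GRID <- c(0.01, seq(0.05, 1, by = 0.05))
.PCTL <- c(1, 5, 10, 25, 50, 75, 90, 95, 99)

#' Fit a shifted Box-Cox transform
#'
#' Selects, over a grid, the Box-Cox exponent minimizing the absolute moment
#' skewness of the transformed daily intakes. The shift is 0 when all values
#' are positive, else half the smallest positive value (so zero-inflated but
#' near-daily nutrients remain in the transform's domain).
#'
#' @param x Nonnegative daily intakes; at least 20 positive values required.
#' @param grid Candidate lambda values in (0, 1].
#' @return A list of class `transform_spec` with `lambda`, `shift`, `grid`.
#' @export
fit_transform <- function(x, grid = .DEFAULT_LAMBDA_GRID) {
  x <- x[!is.na(x)]
  if (sum(x > 0) < 20) {
    abort_ds("need at least 20 positive observations to fit a transform",
             "dietshift_estimation")
  }
  shift <- if (all(x > 0)) 0 else min(x[x > 0]) / 2
  skews <- vapply(grid, function(l) abs(moment_skewness(((x + shift)^l - 1) / l)),
                  numeric(1))
  structure(list(lambda = grid[which.min(skews)], shift = shift, grid = grid),
            class = "transform_spec")
}

#' @rdname fit_transform
#' @param spec A `transform_spec`.
#' @export
bc_transform <- function(x, spec) ((x + spec$shift)^spec$lambda - 1) / spec$lambda

#' @rdname fit_transform
#' @param y Transformed-scale values.
#' @export
bc_inverse <- function(y, spec) {
  base <- pmax(1 + spec$lambda * y, 0)
  pmax(base^(1 / spec$lambda) - spec$shift, 0)
}

#' Method-of-moments variance components for repeated recalls
#'
#' Decomposes transformed person-day values into a day-sequence fixed effect
#' (`beta_day2 = mean(day 2) - mean(day 1)`), within-person variance (half
#' the mean squared within-person day difference after removing the day
#' effect), and between-person variance (the person-mean variance minus its
#' within-person contribution, floored at 0). The transformed-scale mean
#' `mu` is the survey-weighted mean of day-effect-adjusted person means.
#'
#' @param y Transformed daily values.
#' @param person_id Person identifier per value.
#' @param day_index Day (1 or 2) per value.
#' @param weights Optional per-value survey weights (constant within person).
#' @return List of class `variance_components`: `mu`, `beta_day2`,
#'   `sigma2_between`, `sigma2_within`, `n_persons`.
#' @export
fit_variance_components <- function(y, person_id, day_index, weights = NULL) {
  stopifnot(length(y) == length(person_id), length(y) == length(day_index))
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(unique(person_id)) < 2) {
    abort_ds("need at least 2 persons", "dietshift_estimation")
  }
  d1 <- day_index == 1L
  d2 <- day_index == 2L
  beta_day2 <- mean(y[d2]) - mean(y[d1])

  # Within: persons observed on both days.
  y1 <- tapply(y[d1], person_id[d1], mean)
  y2 <- tapply(y[d2], person_id[d2], mean)
  both <- intersect(names(y1), names(y2))
  if (length(both) == 0) {
    abort_ds("no person with two recall days; within-person variance unidentified",
             "dietshift_estimation")
  }
  diffs <- y2[both] - y1[both] - beta_day2
  sigma2_within <- mean(diffs^2) / 2

  y_adj <- y - beta_day2 * (day_index == 2L)
  m <- tapply(y_adj, person_id, mean)
  d_p <- tapply(y_adj, person_id, length)
  w_p <- tapply(weights, person_id, mean)
  sigma2_between <- max(0, stats::var(as.vector(m)) - sigma2_within * mean(1 / d_p))
  mu <- weighted_mean(as.vector(m), as.vector(w_p))
  structure(
    list(mu = mu, beta_day2 = beta_day2, sigma2_between = sigma2_between,
         sigma2_within = sigma2_within, n_persons = length(m)),
    class = "variance_components"
  )
}

#' Simulate the population usual-intake distribution
#'
#' Draws `n_mc` pseudo-persons by resampling the observed persons (carrying
#' their ages, sexes and day-1 weights), assigns each a person effect
#' `b ~ N(0, sigma2_between)`, and computes the usual intake as the expected
#' back-transformed value over the within-person error by `gh_nodes`-point
#' Gauss-Hermite quadrature of the inverse transform at
#' `mu + beta_day2/2 + b + e`, `e ~ N(0, sigma2_within)`. The half day
#' effect centers the estimate between the two recall days. Summary
#' statistics are survey-weight aware.
#'
#' @param vc A [fit_variance_components()] result.
#' @param transform A [fit_transform()] spec.
#' @param persons Tibble with `person_id`, `age_years`, `sex`, `day1_weight`.
#' @param n_mc Number of Monte-Carlo pseudo-persons (>= 100).
#' @param seed RNG seed (summaries are identical for identical seeds).
#' @param gh_nodes Gauss-Hermite node count.
#' @return A list of class `usual_intake_summary`: `nutrient`, `mean`,
#'   `percentiles`, `sample` (pseudo-person tibble with `usual` and
#'   `weight`), `n_persons`, `vc`, `transform`.
#' @export
usual_distribution <- function(vc, transform, persons, n_mc = 10000, seed = 1,
                               gh_nodes = 9) {
  if (n_mc < 100) abort_ds("n_mc must be >= 100", "dietshift_config")
  gh <- pracma::gaussHermite(gh_nodes)
  sw <- sqrt(vc$sigma2_within)
  sb <- sqrt(vc$sigma2_between)
  center <- vc$mu + vc$beta_day2 / 2
  sample_tbl <- withr::with_seed(seed, {
    idx <- sample.int(nrow(persons), n_mc, replace = TRUE)
    b <- stats::rnorm(n_mc, 0, sb)
    nodes <- center + b %o% rep(1, gh_nodes) +
      sqrt(2) * sw * rep(1, n_mc) %o% gh$x
    usual <- as.vector(bc_inverse(nodes, transform) %*% gh$w) / sqrt(pi)
    tibble::tibble(
      person_id = persons$person_id[idx],
      age_years = persons$age_years[idx],
      sex = persons$sex[idx],
      weight = persons$day1_weight[idx],
      usual = usual
    )
  })
  structure(
    list(
      nutrient = NA_character_,
      mean = weighted_mean(sample_tbl$usual, sample_tbl$weight),
      percentiles = stats::setNames(
        weighted_quantile(sample_tbl$usual, sample_tbl$weight, .PCTL / 100),
        paste0("p", .PCTL)
      ),
      sample = sample_tbl,
      n_persons = nrow(persons),
      vc = vc, transform = transform
    ),
    class = "usual_intake_summary"
  )
}

#' Estimate the usual-intake distribution of one nutrient
#'
#' Convenience wrapper: sums recall items to person-day intakes in the
#' requested scope, fits the transform and variance components, and
#' simulates the usual-intake distribution.
#'
#' @param recalls A validated recall tibble.
#' @param nutrient One nutrient key, see [nutrient_keys()].
#' @param scope `"whole_day"` or `"breakfast_only"`.
#' @inheritParams usual_distribution
#' @param grid Lambda grid for [fit_transform()].
#' @return A `usual_intake_summary` (see [usual_distribution()]).
#' @export
estimate_usual_intake <- function(recalls, nutrient, scope = "whole_day",
                                  n_mc = 10000, seed = 1, gh_nodes = 9,
                                  grid = .DEFAULT_LAMBDA_GRID) {
  stopifnot(nutrient %in% nutrient_keys())
  days <- sum_nutrients(recalls, scope)
  x <- days[[nutrient]]
  tr <- fit_transform(x, grid)
  vc <- fit_variance_components(bc_transform(x, tr), days$person_id,
                                days$day_index, days$day1_weight)
  out <- usual_distribution(vc, tr, recall_persons(recalls), n_mc = n_mc,
                            seed = seed, gh_nodes = gh_nodes)
  out$nutrient <- nutrient
  out
}

#' Stratified PSU bootstrap standard errors
#'
#' Resamples primary sampling units with replacement within strata,
#' re-running an arbitrary estimator on each replicate collection (resampled
#' persons are re-keyed so a PSU drawn twice contributes twice). The SD of
#' the replicate statistics estimates the design-based SE; the 2.5/97.5
#' replicate percentiles give a percentile 95% CI. Replicate `b` uses seed
#' `seed + b`, so enlarging `B` extends the replicate stream without
#' changing earlier replicates.
#'
#' @param recalls A validated recall tibble.
#' @param estimator Function `recalls -> named numeric vector`.
#' @param B Number of bootstrap replicates (>= 50).
#' @param seed Base RNG seed.
#' @return List with `se` (named numeric), `ci` (2 x p matrix, rows
#'   `lcl`/`ucl`), and `replicates` (B x p matrix).
#' @export
bootstrap_se <- function(recalls, estimator, B = 100, seed = 1) {
  if (B < 50) abort_ds("B must be >= 50", "dietshift_config")
  recalls <- tibble::as_tibble(recalls)
  design <- dplyr::distinct(recalls, .data$stratum_id, .data$psu_id)
  per_stratum <- split(design$psu_id, design$stratum_id)
  singles <- names(per_stratum)[vapply(per_stratum, length, integer(1)) < 2]
  if (length(singles) > 0) {
    abort_ds(paste0("stratum with a single PSU: ", paste(singles, collapse = ", ")),
             "dietshift_design")
  }
  by_psu <- split(seq_len(nrow(recalls)), recalls$psu_id)
  reps <- lapply(seq_len(B), function(b) {
    rep_rows <- withr::with_seed(seed + b, {
      draws <- unlist(lapply(per_stratum, function(psus) {
        psus[sample.int(length(psus), length(psus), replace = TRUE)]
      }), use.names = FALSE)
      pieces <- lapply(seq_along(draws), function(j) {
        piece <- recalls[by_psu[[draws[j]]], , drop = FALSE]
        piece$person_id <- paste0(piece$person_id, "#", j)
        piece
      })
      dplyr::bind_rows(pieces)
    })
    estimator(rep_rows)
  })
  mat <- do.call(rbind, reps)
  list(
    se = apply(mat, 2, stats::sd),
    ci = apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE) |>
      (\(m) {rownames(m) <- c("lcl", "ucl"); m})(),
    replicates = mat
  )
}
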