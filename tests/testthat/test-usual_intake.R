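test_that("transform selection finds log-like and identity-like scales", {
  set.seed(1)
  x <- exp(rnorm(4000, log(100), 0.6))
  expect_equal(fit_transform(x)$lambda, 0.01)
  set.seed(2)
  z <- rnorm(4000, 100, 10)
  expect_equal(fit_transform(z)$lambda, 1)
  # shift engages only in the presence of zeros
  expect_equal(fit_transform(x)$shift, 0)
  xz <- c(x, 0, 0)
  expect_equal(fit_transform(xz)$shift, min(x) / 2)
  expect_error(fit_transform(rep(0, 100)), class = "dietshift_estimation")
  # transforms invert exactly on their domain
  tr <- fit_transform(x)
  expect_equal(bc_inverse(bc_transform(x, tr), tr), x, tolerance = 1e-9)
})

test_that("variance components match hand-computed ANOVA arithmetic", {
  # two persons, two days; all within-person change is the day effect
  vc <- fit_variance_components(c(1, 2, 3, 4), c("a", "a", "b", "b"),
                                c(1L, 2L, 1L, 2L))
  expect_equal(vc$beta_day2, 1)
  expect_equal(vc$sigma2_within, 0)
  expect_equal(vc$sigma2_between, 2)
  expect_equal(vc$mu, 2)

  # residual within-person scatter after removing the day effect
  vc <- fit_variance_components(c(0, 2, 4, 4), c("a", "a", "b", "b"),
                                c(1L, 2L, 1L, 2L))
  expect_equal(vc$beta_day2, 1)
  expect_equal(vc$sigma2_within, 0.5)
  expect_equal(vc$sigma2_between, 4.25)
  expect_equal(vc$mu, 2)

  expect_error(
    fit_variance_components(c(1, 2), c("a", "b"), c(1L, 1L)),
    class = "dietshift_estimation"
  )
})

test_that("known log-scale variance components are recovered within MC error", {
  set.seed(7)
  n <- 2000
  b <- rnorm(n, 0, 0.3)
  y <- c(b + rnorm(n, 0, 0.5), b + rnorm(n, 0, 0.5))
  vc <- fit_variance_components(y, rep(sprintf("p%04d", 1:n), 2),
                                rep(1:2, each = n))
  # 3 x analytic SE: SE(sw2) ~ sw^2 sqrt(2/n); SE(sb2) ~ sqrt(2) (sb2+sw2/2)/sqrt(n)
  expect_lt(abs(vc$sigma2_within - 0.25), 3 * 0.25 * sqrt(2 / n))
  expect_lt(abs(vc$sigma2_between - 0.09), 3 * sqrt(2) * (0.09 + 0.125) / sqrt(n))
})

test_that("degenerate variance collapses the usual distribution to a point", {
  vc <- structure(list(mu = 5, beta_day2 = 0.4, sigma2_between = 0,
                       sigma2_within = 0, n_persons = 10),
                  class = "variance_components")
  tr <- structure(list(lambda = 0.5, shift = 0), class = "transform_spec")
  persons <- tibble::tibble(person_id = sprintf("p%d", 1:10),
                            age_years = 10L, sex = "male", day1_weight = 1)
  u <- usual_distribution(vc, tr, persons, n_mc = 500, seed = 3)
  expect_equal(unique(u$sample$usual), bc_inverse(5.2, tr))
  expect_equal(sd(u$sample$usual), 0)
  expect_equal(unname(u$percentiles["p50"]), bc_inverse(5.2, tr))
})

test_that("usual-intake mean matches the closed-form lognormal mean", {
  set.seed(11)
  n <- 4000
  mu <- log(100); sb <- 0.3; sw <- 0.5
  b <- rnorm(n, 0, sb)
  x <- exp(mu + c(b + rnorm(n, 0, sw), b + rnorm(n, 0, sw)))
  recalls <- dplyr::bind_cols(
    tibble::tibble(
      person_id = rep(sprintf("p%04d", 1:n), 2), age_years = 10L, sex = "male",
      day1_weight = 1, stratum_id = "ST1",
      psu_id = rep(sprintf("PSU%02d", 1:4), length.out = 2 * n),
      day_index = rep(1:2, each = n), occasion_code = "other",
      food_code = "f", amount = 1,
      milk_fat_level = NA_character_, milk_flavored = NA
    ),
    tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(0, 2 * n, 37, dimnames = list(NULL, nutrient_keys()))),
      nutrient_keys()
    ))
  )
  recalls$choline_mg <- x
  u <- estimate_usual_intake(recalls, "choline_mg", n_mc = 10000, seed = 5)
  truth <- exp(mu + sb^2 / 2 + sw^2 / 2)
  expect_lt(abs(u$mean - truth) / truth, 0.02)

  # mean preservation: the bias-corrected mean tracks the mean daily intake;
  # a naive plug-in back-transform of mu + b must fail on skewed data
  daily_mean <- mean(x)
  expect_lt(abs(u$mean - daily_mean) / daily_mean, 0.03)
  naive <- mean(bc_inverse(u$vc$mu + u$vc$beta_day2 / 2 +
                             rnorm(10000, 0, sqrt(u$vc$sigma2_between)),
                           u$transform))
  expect_gt(abs(naive - daily_mean) / daily_mean, 0.05)

  # shrinkage: usual intakes vary strictly less than single days
  expect_lt(var(u$sample$usual), var(x))

  # determinism and weight-scale invariance
  u2 <- estimate_usual_intake(recalls, "choline_mg", n_mc = 10000, seed = 5)
  expect_equal(u$mean, u2$mean)
  expect_equal(u$percentiles, u2$percentiles)
  scaled <- recalls; scaled$day1_weight <- scaled$day1_weight * 10
  u3 <- estimate_usual_intake(scaled, "choline_mg", n_mc = 10000, seed = 5)
  expect_equal(u3$mean, u$mean)
  # person-order invariance: shuffling input rows changes nothing
  shuffled <- recalls[sample.int(nrow(recalls)), ]
  u4 <- estimate_usual_intake(shuffled, "choline_mg", n_mc = 10000, seed = 5)
  expect_equal(u4$mean, u$mean)
})

test_that("percentiles are nondecreasing and bracket the mean", {
  recalls <- generate_recalls(generator_config(n_persons = 150, seed = 9))
  u <- estimate_usual_intake(recalls, "vit_d_mcg", n_mc = 2000, seed = 2)
  expect_true(all(diff(u$percentiles) >= 0))
  expect_gte(u$mean, min(u$sample$usual))
  expect_lte(u$mean, max(u$sample$usual))
})

bootstrap_fixture <- function(n = 150, seed = 23, constant = FALSE) {
  set.seed(seed)
  vals <- if (constant) rep(5, n) else rlnorm(n, log(100), 0.4)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_item(person_id = sprintf("p%03d", i), stratum_id = "ST1",
              psu_id = sprintf("PSU%03d", i), occasion_code = "other",
              food_code = "f", choline_mg = vals[i])
  }))
}

test_that("PSU bootstrap of a weighted mean agrees with the closed-form SE", {
  recalls <- bootstrap_fixture()
  est <- function(rc) {
    d <- sum_nutrients(rc, "whole_day")
    c(mean = weighted.mean(d$choline_mg, d$day1_weight))
  }
  boot <- bootstrap_se(recalls, est, B = 200, seed = 4)
  d <- sum_nutrients(recalls, "whole_day")
  closed <- sd(d$choline_mg) / sqrt(nrow(d))
  expect_lt(abs(boot$se[["mean"]] - closed) / closed, 0.15)
  expect_true(boot$ci["lcl", 1] < mean(d$choline_mg),
              boot$ci["ucl", 1] > mean(d$choline_mg))
})

test_that("bootstrap replicate stream is prefix-stable and degenerate-safe", {
  recalls <- bootstrap_fixture(n = 40)
  est <- function(rc) c(m = mean(sum_nutrients(rc)$choline_mg))
  b50 <- bootstrap_se(recalls, est, B = 50, seed = 8)
  b51 <- bootstrap_se(recalls, est, B = 51, seed = 8)
  expect_equal(b51$replicates[1:50, , drop = FALSE], b50$replicates)

  const <- bootstrap_fixture(n = 40, constant = TRUE)
  expect_equal(unname(bootstrap_se(const, est, B = 50, seed = 1)$se), 0)

  single <- recalls
  single$stratum_id[single$psu_id == "PSU001"] <- "LONE"
  expect_error(bootstrap_se(single, est, B = 50, seed = 1),
               regexp = "LONE", class = "dietshift_design")
})
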