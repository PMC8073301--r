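# Pipeline orchestration: simulate -> classify -> apply -> usual -> adequacy,
# with table-shaped rendering. Every random stage derives its seed from the
# single config seed, so a fixed config reproduces the bundle exactly.

#' Pipeline configuration
#'
#' @param generator A [generator_config()] for the synthetic cohort, or
#'   `NULL` when `recalls` is supplied.
#' @param recalls Optional recall tibble or CSV path; overrides `generator`.
#' @param scenarios Scenario ids to run (baseline `"S0_baseline"` is always
#'   included and used as the comparison anchor).
#' @param nutrients Nutrient keys to tabulate.
#' @param n_mc Monte-Carlo pseudo-persons per usual-intake distribution.
#' @param B Bootstrap replicates for SEs/CIs on adequacy metrics and the
#'   usual-intake means of DRI nutrients; `0` disables the bootstrap (point
#'   estimates only).
#' @param n_mc_boot Monte-Carlo size used inside bootstrap replicates.
#' @param seed Master seed.
#' @param gh_nodes Gauss-Hermite node count.
#' @param egg_profile_path,dri_path,cacfp_rules_path Optional resource
#'   overrides.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            recalls = NULL,
                            scenarios = c("S1_plus1", "S2_plus2",
                                          "S3_cacfp_plus1", "S4_cacfp_plus2"),
                            nutrients = nutrient_keys(),
                            n_mc = 5000, B = 0, n_mc_boot = 1000,
                            seed = 1L, gh_nodes = 9,
                            egg_profile_path = NULL, dri_path = NULL,
                            cacfp_rules_path = NULL) {
  scenarios <- union("S0_baseline", vapply(scenarios, function(s) scenario_spec(s)$id,
                                           character(1)))
  stopifnot(all(nutrients %in% nutrient_keys()))
  if (B != 0 && B < 50) abort_ds("B must be 0 or >= 50", "dietshift_config")
  structure(
    list(generator = generator, recalls = recalls, scenarios = scenarios,
         nutrients = nutrients, n_mc = n_mc, B = B, n_mc_boot = n_mc_boot,
         seed = as.integer(seed), gh_nodes = gh_nodes,
         egg_profile_path = egg_profile_path, dri_path = dri_path,
         cacfp_rules_path = cacfp_rules_path),
    class = "pipeline_config"
  )
}

.mc_seed <- function(seed, nutrient) {
  (seed * 97L + match(nutrient, nutrient_keys()) * 131L) %% 2000000000L
}

#' Run the full modeling pipeline
#'
#' Generates (or loads) the recall collection, classifies breakfast status,
#' applies each scenario, estimates per-nutrient usual-intake distributions,
#' computes adequacy metrics for nutrients with DRI entries plus the sodium
#' and saturated-fat cutoffs, flags >=10%/>=20% changes versus baseline, and
#' (when `B > 0`) attaches stratified-PSU-bootstrap SEs with normal 95% CIs
#' and CI-overlap significance calls.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_bundle` with elements `usual` (tibble:
#'   scenario, nutrient, mean, se, flag), `adequacy` (tibble: scenario,
#'   nutrient, metric, estimate, se, lcl, ucl, ci_significant), `counts`
#'   (stage log: persons, eligible persons, modified person-days per
#'   scenario), and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  recalls <- config$recalls
  if (is.null(recalls)) {
    recalls <- generate_recalls(config$generator)
  } else if (is.character(recalls)) {
    recalls <- read_recalls(recalls)
  } else {
    validate_recalls(recalls)
  }
  rules <- cacfp_rules(config$cacfp_rules_path)
  profile <- egg_profile(config$egg_profile_path)
  dri <- dri_table(config$dri_path)
  status <- person_status(recalls, rules)

  counts <- list(n_persons = nrow(status),
                 n_egg_free_breakfast = sum(status$has_breakfast & !status$egg_at_breakfast),
                 n_cacfp_compliant = sum(status$cacfp_compliant))
  modified <- lapply(config$scenarios, function(id) {
    apply_scenario(recalls, id, status, profile)
  })
  names(modified) <- config$scenarios
  counts$modified_person_days <- vapply(modified, function(m) {
    sum(m$food_code == "egg_synthetic")
  }, numeric(1))

  dri_nutrients <- intersect(config$nutrients, unique(dri$nutrient))
  usual_rows <- list()
  adequacy_rows <- list()
  usual_cache <- list()
  for (sc in config$scenarios) {
    for (nu in config$nutrients) {
      u <- estimate_usual_intake(modified[[sc]], nu, n_mc = config$n_mc,
                                 seed = .mc_seed(config$seed, nu),
                                 gh_nodes = config$gh_nodes)
      usual_cache[[paste(sc, nu)]] <- u
      usual_rows[[paste(sc, nu)]] <- tibble::tibble(
        scenario = sc, nutrient = nu, mean = u$mean, se = NA_real_
      )
    }
  }

  metric_for <- function(nu) {
    rt <- dri$reference_type[dri$nutrient == nu][1]
    if (rt == "EAR") "pct_below_EAR" else "pct_above_AI"
  }
  point_metric <- function(u, metric, sc) {
    switch(metric,
      pct_below_EAR = pct_below_ear(u, dri)$estimate,
      pct_above_AI = pct_above_ai(u, dri)$estimate,
      pct_above_sodium = pct_above_cutoff(u, "sodium")$estimate,
      pct_above_sat_fat_energy = pct_above_cutoff(
        u, "sat_fat_energy",
        usual_cache[[paste(sc, "energy_kcal")]]
      )$estimate
    )
  }
  cutoff_metrics <- c(
    if ("sodium_mg" %in% config$nutrients) "pct_above_sodium",
    if (all(c("sat_fat_g", "energy_kcal") %in% config$nutrients))
      "pct_above_sat_fat_energy"
  )
  tasks <- dplyr::bind_rows(
    if (length(dri_nutrients) > 0) {
      tibble::tibble(nutrient = dri_nutrients,
                     metric = vapply(dri_nutrients, metric_for, character(1)))
    },
    if ("pct_above_sodium" %in% cutoff_metrics)
      tibble::tibble(nutrient = "sodium_mg", metric = "pct_above_sodium"),
    if ("pct_above_sat_fat_energy" %in% cutoff_metrics)
      tibble::tibble(nutrient = "sat_fat_g", metric = "pct_above_sat_fat_energy")
  )
  if (!is.null(tasks) && nrow(tasks) > 0) {
    for (i in seq_len(nrow(tasks))) {
      nu <- tasks$nutrient[i]; met <- tasks$metric[i]
      for (sc in config$scenarios) {
        est <- point_metric(usual_cache[[paste(sc, nu)]], met, sc)
        se <- NA_real_; lcl <- NA_real_; ucl <- NA_real_
        if (config$B > 0) {
          boot <- bootstrap_se(recalls, function(rc) {
            st <- person_status(rc, rules)
            mod <- apply_scenario(rc, sc, st, profile)
            u <- estimate_usual_intake(mod, nu, n_mc = config$n_mc_boot,
                                       seed = .mc_seed(config$seed, nu),
                                       gh_nodes = config$gh_nodes)
            ur <- if (met == "pct_above_sat_fat_energy") {
              ue <- estimate_usual_intake(mod, "energy_kcal",
                                          n_mc = config$n_mc_boot,
                                          seed = .mc_seed(config$seed, "energy_kcal"),
                                          gh_nodes = config$gh_nodes)
              pct_above_cutoff(u, "sat_fat_energy", ue)$estimate
            } else {
              switch(met,
                pct_below_EAR = pct_below_ear(u, dri)$estimate,
                pct_above_AI = pct_above_ai(u, dri)$estimate,
                pct_above_sodium = pct_above_cutoff(u, "sodium")$estimate)
            }
            c(est = ur)
          }, B = config$B, seed = config$seed)
          se <- unname(boot$se)
          ci <- normal_ci(est, se)
          lcl <- ci[["lcl"]]; ucl <- ci[["ucl"]]
        }
        adequacy_rows[[paste(sc, nu, met)]] <- tibble::tibble(
          scenario = sc, nutrient = nu, metric = met, estimate = est,
          se = se, lcl = lcl, ucl = ucl
        )
      }
    }
  }

  usual <- dplyr::bind_rows(usual_rows)
  base_means <- usual$mean[usual$scenario == "S0_baseline"]
  names(base_means) <- usual$nutrient[usual$scenario == "S0_baseline"]
  usual$flag <- unname(mapply(function(sc, nu, m) {
    if (sc == "S0_baseline") "none" else change_flag(base_means[[nu]], m)
  }, usual$scenario, usual$nutrient, usual$mean))

  adequacy <- dplyr::bind_rows(adequacy_rows)
  if (nrow(adequacy) > 0 && config$B > 0) {
    # significance is reported against two anchors: the baseline and (when
    # present) the one-egg scenario, covering both published conventions
    sig_vs <- function(anchor) {
      vapply(seq_len(nrow(adequacy)), function(i) {
        if (adequacy$scenario[i] == anchor) return(FALSE)
        ref <- adequacy[adequacy$scenario == anchor &
                          adequacy$nutrient == adequacy$nutrient[i] &
                          adequacy$metric == adequacy$metric[i], , drop = FALSE]
        if (nrow(ref) == 0) return(NA)
        ci_overlap_call(c(ref$lcl, ref$ucl), c(adequacy$lcl[i], adequacy$ucl[i]))
      }, logical(1))
    }
    adequacy$ci_significant <- sig_vs("S0_baseline")
    if ("S1_plus1" %in% adequacy$scenario) {
      adequacy$ci_significant_vs_s1 <- sig_vs("S1_plus1")
    }
  } else if (nrow(adequacy) > 0) {
    adequacy$ci_significant <- NA
  }

  structure(list(usual = usual, adequacy = adequacy, counts = counts,
                 config = config),
            class = "pipeline_bundle")
}

.fmt_value <- function(x) {
  ifelse(abs(x) >= 100, sprintf("%.0f", x),
         ifelse(abs(x) >= 10, sprintf("%.1f", x),
                ifelse(abs(x) >= 0.1, sprintf("%.2f", x), signif(x, 2))))
}

.flag_mark <- function(flag) c(none = "", ge10 = " *", ge20 = " **")[flag]

#' Render pipeline results as a delimited table
#'
#' `style = "table1"` gives the usual-intake layout: one row per nutrient,
#' a mean column per scenario with `*` / `**` appended for >=10% / >=20%
#' changes versus baseline, plus SE columns when the bootstrap ran.
#' `style = "table3"` gives the adequacy layout: estimate, SE, LCL, UCL per
#' scenario with `*` marking non-overlapping 95% CIs versus baseline.
#'
#' @param bundle A [run_pipeline()] result.
#' @param style `"table1"` or `"table3"`.
#' @return A tibble of formatted character columns (render with
#'   `readr::write_tsv()` or similar).
#' @export
render_table <- function(bundle, style = c("table1", "table3")) {
  style <- match.arg(style)
  info <- nutrient_info()
  if (style == "table1") {
    wide <- bundle$usual |>
      dplyr::mutate(cell = paste0(.fmt_value(.data$mean), .flag_mark(.data$flag))) |>
      dplyr::select("scenario", "nutrient", "cell") |>
      tidyr::pivot_wider(names_from = "scenario", values_from = "cell")
    wide$Nutrient <- paste0(
      info$label[match(wide$nutrient, info$key)],
      " (", info$unit[match(wide$nutrient, info$key)], ")"
    )
    return(wide[, c("Nutrient", setdiff(names(wide), c("Nutrient", "nutrient")))])
  }
  if (nrow(bundle$adequacy) == 0) {
    abort_ds("no adequacy results in bundle", "dietshift_reporting")
  }
  adequacy <- bundle$adequacy |>
    dplyr::mutate(
      label = paste0(info$label[match(.data$nutrient, info$key)], " [", .data$metric, "]"),
      cell = paste0(
        .fmt_value(.data$estimate),
        ifelse(!is.na(.data$ci_significant) & .data$ci_significant, " *", ""),
        ifelse(is.na(.data$se), "",
               sprintf(" (SE %.1f, CI %.1f-%.1f)", .data$se, .data$lcl, .data$ucl))
      )
    ) |>
    dplyr::select("label", "scenario", "cell") |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "cell")
  adequacy
}

#' Serialize a pipeline bundle to JSON
#'
#' @param bundle A [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle_json <- function(bundle, path) {
  jsonlite::write_json(
    list(usual = bundle$usual, adequacy = bundle$adequacy,
         counts = bundle$counts),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
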