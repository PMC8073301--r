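# Published worked-example tables bundled as plain-text resources: national
# usual-intake means with their printed >=10%/>=20% change annotations, and
# adequacy percentages with printed SEs and 95% confidence limits. They are
# reference inputs for exercising the flagging, CI-construction and
# CI-overlap operations on real printed numbers.

#' Worked-example usual-intake table
#'
#' Published population usual-intake means (baseline, +1 egg, +2 eggs, with
#' SEs) for a general child cohort (`table = "t1"`) and a CACFP-breakfast
#' subgroup (`table = "t2"`), together with the change annotations as
#' printed (`none`/`ge10`/`ge20`).
#'
#' @return Tibble with columns `table`, `nutrient`, `baseline`, `se0`,
#'   `plus1`, `flag1`, `se1`, `plus2`, `flag2`, `se2`.
#' @export
example_usual_table <- function() {
  readr::read_csv(
    system.file("extdata", "example_usual_intakes.csv", package = "dietshift"),
    col_types = readr::cols(
      table = readr::col_character(), nutrient = readr::col_character(),
      flag1 = readr::col_character(), flag2 = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Worked-example adequacy table
#'
#' Published percent-above-AI / percent-below-EAR estimates with SEs and
#' 95% confidence limits for baseline, +1 egg and +2 egg scenarios, plus the
#' printed significance annotations (`none`, `vs_baseline`, `vs_scenario1`).
#'
#' @return Tibble with one row per (metric, nutrient).
#' @export
example_adequacy_table <- function() {
  readr::read_csv(
    system.file("extdata", "example_adequacy.csv", package = "dietshift"),
    col_types = readr::cols(
      metric = readr::col_character(), nutrient = readr::col_character(),
      sig1 = readr::col_character(), sig2 = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
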