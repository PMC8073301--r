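Package: dietshift
Title: Food-Pattern Scenario Modeling and Usual Nutrient Intake Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dietary food-pattern scenario modeling from repeated
    24-hour recall data. Classifies breakfast occasions against USDA Child and
    Adult Care Food Program (CACFP) component rules, adds nutrient-profile
    equivalents of foods (eggs) to eligible breakfasts under modeling
    scenarios, estimates population usual-intake distributions with a
    measurement-error random-effects model (shifted Box-Cox transform,
    method-of-moments variance components, Gauss-Hermite back-transformation),
    and reports nutrient adequacy as the percent of the population below an
    Estimated Average Requirement or above an Adequate Intake, with stratified
    PSU bootstrap standard errors, normal confidence intervals, CI-overlap
    significance calls, and percent-change flags. Includes a synthetic recall
    generator emulating the between-/within-person structure of survey dietary
    data so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
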