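Package: eacrisk
Title: Absolute Risk of Esophageal Adenocarcinoma with Competing Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates an individual's 10-year absolute risk of esophageal
    adenocarcinoma (EAC), adjusted for competing mortality, from age-, sex-
    and race-specific incidence and mortality rate tables and multiplicative
    relative-risk factor sets stratified by Barrett's esophagus status. The
    baseline hazard is derived from population incidence via the population
    attributable risk, confidence intervals use delta-method propagation of
    relative-risk uncertainty, and a companion pipeline evaluates
    discrimination (weighted sensitivity, specificity, positive predictive
    value and AUC) on case-control data with constrained assignment of
    unmeasured covariates, hot-deck multiple imputation and post-stratified
    control weights. Includes a synthetic-data generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
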