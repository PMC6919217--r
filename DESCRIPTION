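Package: icusurv
Title: Conditional Survival Analysis for Intensive Care Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the probability of survival to hospital discharge for
    ICU patients conditional on the number of days already spent in intensive
    care. Provides per-day conditional survival curves with Agresti-Coull
    binomial confidence intervals and a minimum-at-risk truncation rule,
    age-stratified analyses, locally weighted (LOESS) presentation smoothing,
    cohort inclusion/exclusion accounting, and a synthetic admission-table
    generator with an analytic conditional-survival oracle so the estimator
    can be validated without access to restricted clinical databases.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
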