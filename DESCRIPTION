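Package: lifespanr
Title: Survival and Aging-Rate Analysis for Rodent Longevity Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of per-animal lifespan tables from rodent longevity
    experiments with a factorial genotype x treatment x sex design.
    Provides Kaplan-Meier estimation, median lifespan and percent-change
    summaries, two-sample log-rank tests, Cox proportional-hazards fitting
    with Efron or Breslow handling of tied deaths, linear lifespan models
    with sex-adjusted group means, a quantile-threshold maximum-lifespan
    test backed by an exact Fisher test, and a non-parametric interval
    estimator of age-specific mortality and aging rates. A Gompertz-Makeham
    cohort simulator supports calibration, power studies and validation
    when raw lifespan records are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival
Config/testthat/edition: 3
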