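Package: ceasurv
Title: Within-Trial Cost-Effectiveness and Budget-Impact Analysis of
    Mammographic Surveillance Frequency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for within-trial economic evaluation of
    reduced-frequency mammographic surveillance after curative breast cancer
    surgery. Simulates two-arm longitudinal trial data with design-driven
    missingness, converts EQ-5D-5L profiles to utility indices via a value-set
    crosswalk table, computes quality-adjusted life years by the
    area-under-the-curve method, assembles per-patient costs under healthcare
    and societal perspectives, performs multiple imputation by chained
    equations with predictive mean matching, estimates incremental costs and
    QALYs by bootstrapped seemingly-unrelated regression with cost-
    effectiveness acceptability curves and net-monetary-benefit summaries,
    and projects national budget impact with deterministic sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
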