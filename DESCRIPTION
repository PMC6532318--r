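Package: msns
Title: Modified Sick Neonatal Score: Scoring, Validation Statistics, and
    Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Modified Sick Neonatal Score (MSNS), an
    eight-parameter bedside disease-severity score (0-16) for neonates
    admitted to resource-limited newborn care units, from raw clinical
    observations. Provides the complete diagnostic-validation toolkit
    used to evaluate such scores: ROC curves oriented for
    low-score-indicates-risk tests, trapezoidal AUC with Hanley-McNeil
    and DeLong confidence intervals, Youden-index cutoff selection,
    sensitivity/specificity/predictive values with Wilson intervals,
    chi-square association tests, tie-corrected Mann-Whitney
    comparisons, and the Buderer sample-size formula for diagnostic
    accuracy studies. A synthetic cohort generator reproduces the
    published score-category frequencies conditional on outcome, with
    exact convolution-based distributions of the total score serving as
    analytic oracles.
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
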