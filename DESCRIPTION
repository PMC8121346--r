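Package: stepdyn
Title: Sudden Gains, Losses and Dynamic-Complexity Early Warning Signals in
    Daily Step-Count Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Idiographic analysis of daily walking behavior from wearable
    step counts. Detects sudden within-person gains and losses in daily step
    level with a recursive-partitioning change-point segmentation and
    median-scaled shift criteria, computes dynamic complexity (the product of
    a fluctuation measure and a distribution measure on backward moving
    windows) as an early-warning signal, and estimates the association
    between local dynamic complexity and the subsequent occurrence of gains
    and losses with discrete-time multilevel event-history models. Includes
    wear-time validity and inclusion filtering, Kalman-smoother imputation of
    missing days, a synthetic cohort generator with known ground truth for
    end-to-end validation, and sensitivity-grid orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    lme4,
    broom,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
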