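Package: curtailr
Title: Curtailment and Stochastic Curtailment for Sum-Scored Screening
    Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequential stopping rules for fixed-length, sum-scored
    screening questionnaires with an integer cutoff, such as the 17-item
    Current Opioid Misuse Measure (COMM, positive at a total score of 9 or
    more). Derives deterministic curtailment boundaries analytically, fits
    per-stage logistic models on training data to build stochastic
    curtailment look-up tables at chosen probability thresholds (with an
    optional monotone-constrained variant), replays complete response
    records through any boundary table, and reports operating
    characteristics: sensitivity and specificity against the full-length
    classification and against an external gold standard, average test
    length, and the percentage of early stops. A latent-severity synthetic
    cohort generator, calibrated to published item moments, makes the whole
    pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
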