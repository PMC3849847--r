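Package: lookback
Title: Lookback-Window Comorbidity Ascertainment and Concordance in Linked
    Hospital Administrative Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating comorbidity ascertainment from linked
    hospital discharge ("administrative") data against a medical-record
    reference standard. Builds index-admission cohorts from person-linked
    admission histories, ascertains a comorbidity (diabetes, ICD-9 250 /
    ICD-10 E10-E14) on the index admission and over configurable lookback
    windows of prior hospitalization history, computes 2x2 concordance
    measures (observed agreement, sensitivity, specificity, predictive
    values, Cohen's kappa, under/over-estimation) with McNemar and
    between-sample tests, and screens and models predictors of false
    negatives and false positives with chi-square/Fisher tests and
    multivariable logistic regression (including a Charlson comorbidity
    index built from a Quan-style ICD code mapping). A synthetic
    linked-data generator emulating two ICD coding eras makes the whole
    pipeline runnable and testable without access to identifiable data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
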