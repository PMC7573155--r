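Package: fcresponse
Title: Predicting Antidepressant Treatment Response from Challenge-Induced
    Functional Connectivity Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for predicting symptom improvement after
    antidepressant therapy from the short-term effect of a pharmacological
    challenge on resting-state functional connectivity. Implements
    exploratory factor analysis of depression questionnaires with
    sampling-adequacy-driven item removal (principal axis factoring,
    Kaiser criterion, Varimax rotation, Anderson-Rubin scores),
    construction of Fisher-z connectivity matrices from region-of-interest
    time series with simultaneous nuisance regression and band-pass
    filtering, network-based statistics with max-component permutation
    inference, and cross-validated prediction of score change from
    weighted connectivity differences using robust bisquare regression,
    including honest versus circular (double-dipping) comparisons. A
    synthetic-data generator with known ground truth (planted factor
    structure and predictive edge subnetwork) makes every stage testable
    without access to clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
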