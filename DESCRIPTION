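Package: emadhere
Title: Adherence Analysis for Smartphone Ecological Momentary Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies user adherence to prompt-based ecological momentary
    assessment (EMA) recording in mobile health apps. Computes interaction
    duration and continuity (days until first break, return after break) from
    long-format EMA tables, builds per-item length strata and classifies
    return-after-break with elastic time-series distances (DTW, derivative DTW,
    complexity-invariant distance, move-split-merge) under a one-nearest-
    neighbour rule, evaluates classifiers against the majority-class prior with
    an improvement cut-off, and induces length-constrained classification rules
    with support, precision, lift and an exact significance filter over
    registration questionnaires. Includes a synthetic cohort generator with
    plantable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    broom,
    withr,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
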