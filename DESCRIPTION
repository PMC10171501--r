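Package: dfcsubtype
Title: Subtype Discovery from Dynamic Functional Connectivity with
    Normative Deviation Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering patient subtypes from
    resting-state regional time series. Computes sliding-window dynamic
    functional connectivity, decomposes it into reference-guided independent
    components with time-varying weights, summarises each subject by graph
    global-efficiency measures and weight fluctuation coefficients, scores
    individual deviations against age-referenced polynomial quantile
    (normative) curves, and clusters patients with wrapper forward feature
    selection and repeated k-means with certainty-based label assignment.
    Includes covariate-adjusted permutation two-sample tests and a fully
    specified synthetic cohort generator with planted ground truth for
    validation.
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
    igraph,
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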