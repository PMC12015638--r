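Package: gradientflow
Title: Dynamic and Static Functional Connectivity Gradient Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Sliding-window functional connectivity gradient analysis for
    parcellated fMRI time series. Builds static and windowed connectivity
    matrices, computes diffusion-map gradients with a normalized-angle kernel,
    discretizes gradients into bins, and quantifies their temporal
    reconfiguration through allegiance, flexibility, and recruitment, with
    phase-randomized static null models, loading scores tying task activation
    to a reference gradient, rank-based covariate-adjusted group comparisons
    with false discovery rate control, and permutation tests of
    activation-gradient coupling. Ships a synthetic cohort generator with a
    planted unimodal-to-transmodal axis, block task design, genuine window
    dynamics, and injectable group effects so every stage has recoverable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
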