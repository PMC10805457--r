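Package: selkmeans
Title: Selective Inference for Differences in Means After K-Means Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact finite-sample tests for a difference in means between two
    clusters estimated by k-means clustering. Classical (naive) tests applied
    to data-derived clusters are anti-conservative because the same data are
    used to form and to test the hypothesis. This package computes a selective
    p-value that conditions on every intermediate assignment of a traced
    Lloyd's algorithm run; the conditioning event reduces to an intersection
    of quadratic inequalities in a one-dimensional perturbation coordinate,
    so the p-value is the survival function of a scaled chi distribution
    truncated to an analytically computed union of intervals. Extensions
    cover a known non-spherical feature covariance (whitening or direct
    conditioning) and unknown noise level via plug-in estimators, together
    with a simulation harness for selective Type I error, detection
    probability and conditional power, and brute-force oracles used in
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
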