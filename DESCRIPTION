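Package: noisecut
Title: Noise-Tolerant Binary Classification over Tree-Structured
    Functional Networks via Exact Max-Cut
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns two-layer tree-structured functional networks (Boolean
    lookup-table 'boxes' over disjoint groups of binary features) from
    labelled binary data, tolerating substantial label noise. Each
    first-layer box function is identified by solving an exact max-cut
    problem on a conflict graph whose edge weights count label-discordant
    sample pairs that differ only in that box's inputs; the output box is
    identified by majority voting. Includes a synthetic benchmark
    generator, a label-noise injector, classification metrics with
    bootstrap confidence intervals, and a noise-sweep experiment harness.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
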