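Package: bltnet
Title: Recurrent Convolutional Networks for Occluded Digit Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a family of small recurrent convolutional neural
    networks with bottom-up (B), lateral (L) and top-down (T) connections
    (presets B, B-F, B-K, BT, BL, BLT), together with a generative model for
    occluded digit stimuli (digit clutter and digit debris), pixel-wise
    normalization and additive Gaussian noise, training by backpropagation
    through time with momentum and an exponentially decaying learning rate,
    multi-label top-n evaluation, and the statistical machinery for comparing
    trained models: pairwise McNemar tests (with a cluster-adjusted variant
    for correlated multi-label outcomes), Benjamini-Hochberg false discovery
    rate control, and a permutation test on robustness slopes. Experiment
    grids over tasks, occlusion levels and architectures can be run at
    configurable scale from R or from a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
SystemRequirements: C++17
Config/testthat/edition: 3
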