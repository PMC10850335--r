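Package: pmmnet
Title: Positional Multi-Length and Mutual-Attention Networks for EEG Seizure Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of single-channel electroencephalogram (EEG)
    segments into seizure and non-seizure states with a positional
    multi-length and mutual-attention (PMM) network: gated residual
    convolutional feature encoding, hierarchically stacked residual dilated
    LSTMs (dilation rates 1, 2, 4), three-way mutual scaled-dot attention
    with multi-head fusion, and a softmax classifier trained with Adam under
    categorical cross-entropy. Includes a tape-based reverse-mode
    differentiation core with finite-difference verification, readers for
    the Bonn per-channel ASCII and UCI seizure-recognition CSV formats,
    a seeded spike-wave EEG simulator with controllable class separability,
    stratified and group-aware k-fold cross-validation, and
    confusion-matrix metrics (accuracy, precision, sensitivity,
    specificity, F1).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
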