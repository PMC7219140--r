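Package: bilstmgc
Title: Neural Granger Causality for Directed Connectivity with Bidirectional LSTM Regressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates directed (effective) connectivity in multichannel time
    series by Granger causality in which the autoregressive predictors are
    neural sequence regressors: a bidirectional stacked LSTM (bi-LSTM-GC)
    able to exploit both past and future context, a unidirectional LSTM
    (RNN-GC), a feed-forward network on flattened lag windows (NN-GC), and a
    classical ordinary-least-squares vector-autoregression oracle. Ships
    three ground-truthed benchmark simulators (linear, nonlinear with long
    delays, and nonlinear with forward/future dependencies), a
    permutation-surrogate edge-detection procedure, and an EEG
    post-processing chain (Chebyshev type-I band filtering, stationarity
    preprocessing, extended 10/20 montage region mapping, stable-dependency
    extraction and region-level flow summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
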