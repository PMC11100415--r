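Package: fitnet
Title: Fusion Inception-Transformer Networks for Continuous Finger
    Kinematics Estimation from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous estimation of finger joint angles from multichannel
    surface electromyography (sEMG). Implements the FIT regressor, a hybrid
    of inception-style multi-scale 1-D convolutions with efficient
    downsampling and pre-layer-norm transformer encoder blocks, together
    with LSTM, temporal convolutional network (TCN) and BERT-style encoder
    baselines, all trained by backpropagation with Adam. Includes a
    synthetic sEMG/kinematics generator with Ninapro DB2 trial structure,
    RMS-envelope and mu-law preprocessing, leakage-safe temporal splits and
    folds, Pearson/R-squared/NRMSE evaluation, and a Friedman plus exact
    Wilcoxon signed-rank model-comparison protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
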