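Package: emgintent
Title: Single-Sensor Surface-EMG Motion-Intent Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Frequency-domain classification of motion intent from a single
    surface electromyography (sEMG) channel. Implements Butterworth band-pass
    conditioning, rectified-envelope extraction and FIR decimation; Welch
    power-spectral-density estimation over sliding windows with four spectral
    features (band power, PSD peak, mean and median frequency); a CART
    decision-tree classifier with Gini impurity, balanced class weights and
    pre-pruning grid search; a median/third-quartile thresholding classifier;
    action-window ground truthing with window-level scoring and stratified
    cross-validation; and a synthetic sEMG generator (band-limited bursts,
    crosstalk, controlled SNR) emulating the acquisition protocols the
    methods target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr,
    yaml
Config/testthat/edition: 3
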