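Package: rhythmeeg
Title: Rhythm- and Time-Scale-Resolved EEG Emotion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for valence/arousal emotion recognition from multichannel
    EEG. Decomposes recordings into canonical frequency rhythms (delta, theta,
    alpha, beta, gamma) by discrete wavelet transform band reconstruction,
    segments each rhythm signal into equal-length rectangular windows at a
    configurable time scale, classifies trials with a gated recurrent (LSTM)
    sequence model trained by backpropagation through time, and evaluates every
    (rhythm, time-scale) pairing with stratified ten-fold cross-validation
    (accuracy, sensitivity, specificity, macro-F1) to identify the pairing that
    recognizes each emotion dimension best. Includes EDF and plain-matrix EEG
    I/O, rating binarization, and a synthetic band-confined-oscillation
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
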