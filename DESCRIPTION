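Package: bohdf
Title: Bag-of-Hybrid-Deep-Features Pipeline for EEG Emotion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a bag-of-hybrid-deep-features (BoHDF) pipeline for
    classifying multi-channel EEG trials into emotion classes: Butterworth
    band-pass preprocessing (4-45 Hz), short-time Fourier transform
    spectrogram images, a rotation-invariant multi-oriented multi-scale
    local binary pattern texture descriptor with joint sign/magnitude/center
    histograms (600 features), pluggable deep-network image features (1000
    features, with a deterministic mock backend), per-class k-means
    bag-of-words encoding, and weighted KNN / SVM classification with
    stratified cross-validation. Ships a synthetic EEG generator with
    class-conditional band-power signatures so the whole pipeline is
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    digest,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
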