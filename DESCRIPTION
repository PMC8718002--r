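Package: floralecho
Title: Echo-Acoustic Traits and Classification of Bat-Pollinated Flowers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of ultrasonic flower echoes for comparing
    pollination syndromes. Generates synthetic flower specimens and
    angle-indexed impulse responses with a calibrated log-linear dependence of
    broadband target strength on flower surface area, recovers impulse
    responses from maximum-length-sequence (MLS) ensonification recordings by
    FFT deconvolution with period averaging, computes plate-calibrated spectral
    target strength in standard frequency bands, estimates bell-shaped flower
    surface area and coefficients of variation of morphological features, fits
    the target-strength regression and syndrome comparisons, and trains a
    multi-input convolutional network on echo spectrograms to classify species
    from one or several echoes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
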