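Package: cottonir
Title: Chemometric and Convolutional Models for Seed Cotton Impurity from NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calibrating near-infrared reflectance spectra of
    machine-picked seed cotton against gravimetric impurity content.
    Implements spectral pretreatments (min-max normalization, standard
    normal variate, Savitzky-Golay smoothing), SPXY joint X-Y distance
    sample-set partitioning, wavelength selection by the successive
    projections algorithm and random frog, PLSR / epsilon-SVR / LSSVM
    calibration models with cross-validated hyperparameter search, and a
    small one-dimensional convolutional network ("Cotton-Net") trained
    with Adam on a logarithmic mean-squared-error loss. A seeded synthetic
    spectra generator emulates a 125-channel 950-1650 nm instrument grid
    so the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
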