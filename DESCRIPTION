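Package: glhmmr
Title: Gaussian-Linear Hidden Markov Models with Variational Inference,
    Permutation Testing and Fisher-Kernel Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Gaussian-linear hidden Markov models (GLHMM), a family of
    hidden Markov models whose Gaussian state distributions are parameterised
    by linear regression, so that unsupervised, encoding and decoding models
    are special cases of one formulation. Estimation is by variational Bayes,
    with an optional stochastic (mini-batch) variant for large data sets, and
    dual estimation for subject-level models. Includes constrained transition
    structures and Viterbi decoding, time-aggregated state statistics
    (fractional occupancy, dwell times, switching rates, occupancy entropy),
    permutation-based association testing with exchangeability blocks in four
    schemes, and out-of-sample prediction of unit-level variables through the
    Fisher kernel or summary-metric features with group-aware nested
    cross-validation and cross-validation-safe deconfounding. A catalogue of
    synthetic benchmark scenarios supports testing and tutorials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
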