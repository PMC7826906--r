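Package: itrfluct
Title: Information Transmission Rate and Fluctuations of Binary Markov
    Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how the information transmission rate
    (entropy rate, bits per symbol) of a two-state Markov information
    source relates to the fluctuation level of its emitted binary
    stream, in the setting of binary-encoded neuronal spike trains.
    Provides the closed-form entropy rate, standard deviation and
    variance of the source as functions of the transition
    probabilities, the quotients ITR/sigma and ITR/variance at fixed
    jumping parameter s with their symmetry, limits, bounds, extrema
    and critical parameters, generalized entropy surrogates (truncated
    Taylor series, unimodal map and its root), a seeded trajectory
    simulator with plug-in block-entropy and RMS estimators, and a
    command-line interface producing curve tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
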