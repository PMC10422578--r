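Package: thermospec
Title: Thermal Time-Constant Spectrometry for Dynamic Infrared Thermography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the discrete spectrum of thermal time constants and
    amplitudes underlying a multi-exponential temperature-rise curve, the
    signal recorded by active (dynamic) infrared thermography of skin after
    contact cooling. The inverse problem is solved by a regression
    convolutional neural network trained exclusively on synthetically
    generated curves from the four-component Foster-network step response,
    with a box-constrained nonlinear least-squares fitter as an independent
    reference method. Includes the synthetic-data generator with a Gaussian
    noise protocol, noise-robustness evaluation, and the normalization and
    physical-unit rescaling pipeline for measured temperature-time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
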