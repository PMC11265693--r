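Package: vepfit
Title: Calibration of Whole-Brain Epileptor Network Models by Cooperative
    Scatter Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the two-dimensional reduction of the Epileptor neural
    mass model on a structural connectome, projects source activity to
    stereo-EEG (SEEG) sensors through an inverse-square gain matrix, and
    calibrates per-region excitability and global coupling against observed
    time series with a cooperative enhanced scatter-search optimizer
    hybridised with dynamic hill-climbing local search. Includes a synthetic
    benchmark generator for six estimation problems (deterministic and
    stochastic, source- and sensor-level observations), ensemble uncertainty
    quantification from the optimizer's solution archive, and
    epileptogenic/propagation/healthy-zone classification scoring.
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
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
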