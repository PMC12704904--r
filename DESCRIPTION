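Package: cupball
Title: Dynamic Stability and Impedance Planning for Cup-and-Ball Manipulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying manipulation of an underactuated cup-and-ball
    object, modeled as a cart with a suspended pendulum. Provides a forced
    cart-pendulum simulator with an equilibrium-trajectory impedance
    controller, Hilbert relative-phase stability metrics (circular variance,
    instantaneous frequency, time to stable phase), effort, smoothness and
    ball-escape-risk measures, strategy landscapes over preparation and
    interaction choices with Kullback-Leibler comparison against behavioral
    choice distributions, a stochastic open-loop optimal control model of
    arm-impedance planning under pendulum-length uncertainty (mean-covariance
    propagation with Ornstein-Uhlenbeck parameter noise), and a synthetic
    participant-cohort generator for end-to-end pipeline testing.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
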