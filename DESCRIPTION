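Package: mdoecarrier
Title: Model-Assisted Design of Experiments for Microcarrier Cell Expansion
Version: 0.1.0
Authors@R:
    person("mdoecarrier", "developers", email = "mdoecarrier@example.org",
           role = c("aut", "cre"))
Description: Kinetic modelling and model-assisted Design of Experiments (mDoE)
    for microcarrier-based expansion of adherent cells in shake flasks. Provides
    a Monod-type batch ODE model with an initial attachment window, carrier
    surface (space) limitation and an unobserved limiting substrate; weighted
    nonlinear least-squares calibration against multi-experiment time series
    with Monte-Carlo parameter uncertainty; classical and optimal experimental
    design generators (central composite, Box-Behnken, Latin hypercube,
    D-optimal, I-optimal, Latin-hypercube-seeded D-optimal); model-based design
    evaluation under parameter uncertainty with a desirability function and
    response-surface-based recommendation of culture conditions; and a synthetic
    shake-flask data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
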