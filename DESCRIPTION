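Package: betapolar
Title: Opinion Polarization Dynamics with Fake-News Compartments and
    Beta-Mixture Equilibria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the joint dynamics of bivariate sentiment
    scores and misinformation spreading in closed online communities. The
    package simulates an N-agent stochastic compromise model with
    bounded-confidence interactions, solves its mean-field nonlinear
    Fokker-Planck limit on the unit square with a structure-preserving
    (Chang-Cooper type) finite-volume scheme, couples the opinion density
    to a Susceptible-Exposed-Infectious-Recovered description of fake-news
    dissemination, derives the stationary Beta and two-component
    Beta-mixture marginals in closed form, and calibrates those mixtures
    to binned sentiment data by bounded nonlinear least squares. A
    synthetic-data generator, the final-size calibration of the contact
    rate, mode diagnostics for polarization, and a small command-line
    front end are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
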