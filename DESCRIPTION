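Package: riskscreen
Title: Simulation of Time-Dependent Risk-Based Screening Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level simulation framework for comparing screening
    allocation strategies that use time-dependent (annual) disease risk
    predictions. Generates populations with correlated annual conditional
    risks, models exponential loss of curability with detection delay,
    calibrates risk-threshold strategies (cumulative, cumulative with
    interval-wise reevaluation, interval-specific) to a target detection
    rate, and quantifies screening examinations saved relative to an
    uninformed random allocation across scenario grids. Also evaluates the
    same strategies on cohorts of per-patient risk predictions with
    observed events and imperfect examination sensitivity, including a
    synthetic cohort generator with lognormal marginals and a Gaussian
    copula for lag-decaying rank correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
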