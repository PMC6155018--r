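Package: myotrap
Title: Single-Molecule Optical Trap Analysis and Crossbridge Ensemble
    Simulation for Cardiac Myosin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dual-beam ("three-bead") optical trapping
    records of single cardiac myosin molecules and for relating single-molecule
    mechanochemistry to ensemble muscle behaviour. Provides a synthetic-data
    generator for dumbbell position/force traces with known ground truth,
    covariance-based binding-event detection with step-size and force
    measurement, time-forward and time-backward ensemble averaging of the
    working stroke, weighted maximum-likelihood fitting of deadtime-censored
    dwell-time and step-size mixtures with bootstrap confidence intervals,
    Bell-equation force-dependence fits, three-parameter EC50 dose-response
    analysis, and a modified-Gillespie Monte Carlo simulator of a cooperatively
    activated thin filament interacting with an ensemble of myosin heads,
    including drug-bound non-stroking subpopulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
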