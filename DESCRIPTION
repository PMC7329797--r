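Package: meroCRRT
Title: Population Pharmacokinetics of Meropenem During Continuous Renal
    Replacement Therapy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population pharmacokinetic analysis of meropenem in
    critically ill patients on continuous renal replacement therapy (CRRT).
    Implements a two-compartment infusion model with CRRT clearance,
    first-order conditional (FOCE-with-interaction style) mixed-effects
    estimation with stepwise covariate selection, visual predictive checks
    and nonparametric bootstrap model evaluation, and Monte Carlo
    probability-of-target-attainment (PTA) simulation for percent-of-interval
    time-above-MIC dosing targets. Includes a synthetic study-cohort
    generator with known ground truth for estimator validation, NONMEM-style
    event-record data input/output, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
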