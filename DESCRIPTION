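Package: radpk
Title: Population Pharmacokinetic Modelling and Simulation of Radotinib
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects pharmacokinetic modelling and simulation
    toolkit built around the published population model of the BCR-ABL1
    tyrosine kinase inhibitor radotinib: a two-compartment disposition model
    with transit-compartment first-order absorption and a circadian (cosine)
    modulation of apparent clearance. Provides NONMEM-style event-table
    input/output, log-normal interindividual and interoccasion variability
    with proportional residual error, a compiled adaptive Runge-Kutta
    simulation engine, Monte Carlo exploration of dosing regimens with
    steady-state exposure metrics, first-order conditional estimation with
    interaction (FOCE-I), empirical Bayes estimates and conditional weighted
    residuals, stepwise covariate modelling, visual predictive checks,
    nonparametric bootstrap, and a synthetic study generator emulating the
    two-cohort healthy-volunteer / CML-CP design used to develop the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
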