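Package: erfate
Title: Autophagy-Apoptosis Crosstalk Dynamics under ER Stress
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and exact-stochastic simulation of a minimal
    regulatory network for the life-or-death decision under endoplasmic
    reticulum stress: an ER stress sensor drives a pro-survival autophagy
    inducer and, through a multistep modification chain, a pro-death
    apoptosis inducer; the two inducers mutually antagonise each other and
    a positive feedback on apoptosis-inducer deactivation renders the death
    decision effectively irreversible. Provides the ODE core, a Gillespie
    single-cell engine, stress protocols (constant treatment, washout,
    autophagy modulation), population fate statistics, bifurcation and
    threshold scans, anchor-based parameter calibration, and synthetic
    immunoblot and apoptotic-index observables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
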