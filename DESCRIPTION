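Package: ddmap
Title: Small-Area Spatio-Temporal Modelling of DDD-Standardised Prescribing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for drug-utilisation disease mapping at small-area level.
    Standardises prescription quantities into WHO defined-daily-dose (DDD)
    equivalents and DDD-per-1000-population rates, builds intrinsic
    conditional autoregressive (ICAR) spatial structures with BYM2 scaling
    factors from area adjacency graphs, and fits an extended BYM2
    spatio-temporal Poisson model by Hamiltonian Monte Carlo with analytic
    gradients. Includes a generative simulator for practice-level
    prescribing records with known ground truth, hold-out validation
    (RMSE and posterior-predictive interval coverage), and MCMC convergence
    diagnostics (split rank-normalised R-hat, effective sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
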