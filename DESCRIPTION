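Package: sispulse
Title: Stochastic SIS Epidemic Extinction Under Pulsed Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying disease extinction in finite populations
    under randomly or periodically scheduled treatment pulses. Implements the
    stochastic SIS model in a constrained one-dimensional form and as the full
    two-dimensional susceptible-infected process, with a bulk treatment channel
    that instantaneously cures a fraction of the infected pool. Mean times to
    extinction are computed by three mutually validating routes: exact Gillespie
    simulation, direct master-equation solves (mean first-passage times,
    quasi-stationary distributions and their decay rates), and a WKB (eikonal)
    approximation built on the Hamiltonian of the scaled jump process, including
    a generalized-Newton solver for the optimal path to extinction, the action
    along it, a small-treatment asymptotic expansion, and mean-time-to-extinction
    prefactors. Scripted experiments compare treatment schedules (Poisson versus
    periodic) and dose allocations at fixed total treatment supply.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
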