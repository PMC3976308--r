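Package: isingflow
Title: Information Flow of Ising Dynamics on Weighted Brain-Like Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo simulation of the Ising model on weighted,
    symmetric networks (square lattices, deterministic scale-free graphs,
    and surrogate two-hemisphere connectomes) under Glauber, Metropolis,
    heat-bath and Wolff dynamics, together with estimation of the directed
    information-flow network among spins via plug-in bivariate transfer
    entropy and its linear Granger-causality approximation. Includes
    thermodynamic observables (susceptibility, heat capacity), spin
    flip-time statistics, diminishing-marginal-returns indicators (the
    global ratio R of outgoing to incoming flow dispersion and the
    per-node ratio r), hemispheric segregation, rich-club coefficients of
    the flow network, degree-preserving null models, and an
    inverse-temperature sweep driver that locates the pseudo-critical
    point of a finite network.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
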