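Package: mfptnet
Title: Mean First-Passage Times on Discrete-State Stochastic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes mean first-passage times (MFPTs) between states of
    arbitrary discrete-state stochastic networks, by the combinatorial Hill
    method (maximal-tree enumeration on a modified network, giving exact
    stationary fluxes) and by Monte Carlo simulation of ensembles of random
    walkers with waiting probabilities and per-edge local times. Includes a
    plain-text network format with exact common-fraction probabilities,
    generators for benchmark topologies (hypercubes, Sierpinski gaskets,
    Bethe lattices, random and fractal scale-free trees), an analysis of
    free-energy transduction between two reactions coupled through a gated
    conformational network (one-way fluxes, degree of coupling, efficiency),
    and favourable-path extraction on MFPT-weighted binding-funnel networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    igraph,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
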