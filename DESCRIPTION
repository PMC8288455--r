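Package: rkcompete
Title: Lotka-Volterra Competition Dynamics of r- and K-Selected Cell
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the competition between r-selected (fast-growing,
    density-sensitive) and K-selected (slow-growing, crowding-tolerant)
    tumor cell populations. Provides a deterministic two-type
    Lotka-Volterra competition model, a stochastic birth-death simulator
    of serial-passage co-cultures with dilution, an on-lattice
    agent-based model of spatial co-growth with density-dependent
    division, death and migration, grid-search estimation of the
    inter-type competition coefficients from fraction-versus-passage
    trajectories, and a synthetic-data generator emulating
    flow-cytometry fraction measurements with binomial gating noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
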