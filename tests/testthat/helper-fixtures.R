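# Small parameter sets shared across tests.

toy_pr <- function(...) {
  phenotype_params("r", intrinsic_rate = 0.04, carrying_capacity = 100, ...)
}

toy_pk <- function(...) {
  phenotype_params("K", intrinsic_rate = 0.03, carrying_capacity = 100, ...)
}

# lattice from a small integer matrix (0 empty, 1 r, 2 K)
toy_lattice <- function(m, time = 0) {
  storage.mode(m) <- "integer"
  structure(m, time = time, class = c("rk_lattice", class(m)))
}

# relative error tolerant of zeros
rel_err <- function(x, y) {
  abs(x - y) / pmax(abs(y), 1e-12)
}
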