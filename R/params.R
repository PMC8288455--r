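#' Per-type life-history parameters
#'
#' Bundles the life-history traits of one cell type. The deterministic
#' Lotka-Volterra model uses only `intrinsic_rate` and `carrying_capacity`;
#' the stochastic passage simulator additionally uses `baseline_death`
#' (density-independent turnover), and the spatial agent-based model uses
#' `density_death_coef` (extra per-hour death rate at full local crowding)
#' and `motility` (per-hour migration attempt rate).
#'
#' @param label Cell type label, `"r"` or `"K"`.
#' @param intrinsic_rate Per-hour net growth rate at vanishing density
#'   (the classical r). Must be positive.
#' @param carrying_capacity Carrying capacity in cells (the classical K).
#'   Must be positive.
#' @param baseline_death Per-hour density-independent death rate (>= 0).
#' @param density_death_coef Per-hour death-rate increment at full local
#'   crowding (>= 0); used by the spatial model.
#' @param motility Per-hour migration attempt rate (>= 0); used by the
#'   spatial model.
#'
#' @return An object of class `phenotype_params`.
#' @examples
#' phenotype_params("r", intrinsic_rate = 0.04, carrying_capacity = 100)
#' @export
phenotype_params <- function(label,
                             intrinsic_rate,
                             carrying_capacity,
                             baseline_death = 0,
                             density_death_coef = 0,
                             motility = 0) {
  label <- match.arg(label, c("r", "K"))
  stopifnot(
    is.numeric(intrinsic_rate), length(intrinsic_rate) == 1L,
    is.finite(intrinsic_rate), intrinsic_rate > 0,
    is.numeric(carrying_capacity), length(carrying_capacity) == 1L,
    is.finite(carrying_capacity), carrying_capacity > 0,
    is.numeric(baseline_death), baseline_death >= 0,
    is.numeric(density_death_coef), density_death_coef >= 0,
    is.numeric(motility), motility >= 0
  )
  structure(
    list(
      label = label,
      intrinsic_rate = intrinsic_rate,
      carrying_capacity = carrying_capacity,
      baseline_death = baseline_death,
      density_death_coef = density_death_coef,
      motility = motility
    ),
    class = "phenotype_params"
  )
}

#' Inter-type competition coefficients
#'
#' `alpha` is the crowding weight of K cells on r cells: one K cell crowds
#' an r cell as much as `alpha` r cells would. `beta` is the reverse
#' (effect of r cells on K cells). Both are dimensionless and non-negative;
#' `alpha = beta = 0` means the two types grow as independent logistics.
#'
#' @param alpha Effect of K cells on r cells (>= 0).
#' @param beta Effect of r cells on K cells (>= 0).
#'
#' @return An object of class `interaction_params`.
#' @examples
#' interaction_params(alpha = 2.2, beta = 0)
#' @export
interaction_params <- function(alpha, beta) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0,
    is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0
  )
  structure(list(alpha = alpha, beta = beta), class = "interaction_params")
}

#' Population state of a two-type culture
#'
#' @param n_r Count of r cells (>= 0; real-valued in the deterministic
#'   model, integer in the stochastic simulators).
#' @param n_K Count of K cells (>= 0).
#' @param time Time in hours (>= 0).
#'
#' @return An object of class `population_state`.
#' @export
population_state <- function(n_r, n_K, time = 0) {
  if (!is.numeric(n_r) || !is.numeric(n_K) ||
      !is.finite(n_r) || !is.finite(n_K) || n_r < 0 || n_K < 0) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(time), is.finite(time), time >= 0)
  structure(list(n_r = n_r, n_K = n_K, time = time),
            class = "population_state")
}

#' Default phenotype parameters for the serial-passage regime
#'
#' Desk-scale calibration of the two life histories for well-mixed
#' high-density passaging: r cells grow faster at low density
#' (0.04 vs 0.03 per hour) while K-selection enhances carrying capacity
#' (the K type holds 95% of the joint capacity). Baseline turnover
#' (0.02 per hour births matched by deaths) sets the demographic noise
#' level. `capacity_total` scales both capacities; 1000 cells is the
#' default desk-scale population, at which the r population's
#' quasi-equilibrium is a handful of cells and demographic drift can
#' absorb it within tens of passages even without interaction.
#'
#' @param capacity_total Joint carrying-capacity scale in cells.
#' @return A list with elements `r` and `K`, both `phenotype_params`.
#' @export
default_passage_phenotypes <- function(capacity_total = 1000) {
  stopifnot(capacity_total > 0)
  list(
    r = phenotype_params("r",
      intrinsic_rate = 0.04,
      carrying_capacity = 0.05 * capacity_total,
      baseline_death = 0.02
    ),
    K = phenotype_params("K",
      intrinsic_rate = 0.03,
      carrying_capacity = 0.95 * capacity_total,
      baseline_death = 0.02
    )
  )
}

#' Default phenotype parameters for the spatial agent-based model
#'
#' Calibration knobs, not measured values: r cells divide fast, die
#' readily under local crowding and are motile; K cells divide slowly,
#' tolerate crowding and are nearly sessile. `carrying_capacity` is not
#' used on the lattice (volume exclusion plays that role) and is set to 1.
#'
#' @return A list with elements `r` and `K`, both `phenotype_params`.
#' @export
default_spatial_phenotypes <- function() {
  list(
    r = phenotype_params("r",
      intrinsic_rate = 0.06,
      carrying_capacity = 1,
      baseline_death = 0.002,
      density_death_coef = 0.10,
      motility = 0.2
    ),
    K = phenotype_params("K",
      intrinsic_rate = 0.025,
      carrying_capacity = 1,
      baseline_death = 0.002,
      density_death_coef = 0.01,
      motility = 0.02
    )
  )
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat(sprintf(
    paste0("<phenotype_params '%s'> intrinsic_rate=%g/h K=%g",
           " baseline_death=%g/h density_death_coef=%g/h motility=%g/h\n"),
    x$label, x$intrinsic_rate, x$carrying_capacity,
    x$baseline_death, x$density_death_coef, x$motility
  ))
  invisible(x)
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf("<interaction_params> alpha=%g beta=%g\n", x$alpha, x$beta))
  invisible(x)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> n_r=%g n_K=%g t=%gh\n",
              x$n_r, x$n_K, x$time))
  invisible(x)
}
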