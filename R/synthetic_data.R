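#' Design of a synthetic flow-cytometry fraction experiment
#'
#' Describes the measurement side of a fraction-vs-passage experiment:
#' how many replicate cultures, how many passages, how many cells are
#' scored (gated) per measurement, and the initial r:K seeding ratio.
#' Gating a finite number of cells makes each measured fraction a
#' binomial proportion around the latent culture fraction.
#'
#' @param n_replicates Replicate cultures (default 3).
#' @param n_passages Passages measured (default 30; a short-format
#'   fitness assay would use 5).
#' @param gated_cells Cells scored per measurement (default 1e4, a
#'   typical flow-cytometry event count).
#' @param init_ratio Initial ratio string `"9:1"`, `"1:1"` or `"1:9"`
#'   (r:K), or any `"a:b"` with positive parts.
#' @param rng_seed Integer seed or `NULL`.
#' @return An object of class `flow_design`.
#' @export
flow_design <- function(n_replicates = 3,
                        n_passages = 30,
                        gated_cells = 1e4,
                        init_ratio = "9:1",
                        rng_seed = NULL) {
  stopifnot(n_replicates >= 1, n_passages >= 1, gated_cells >= 1)
  frac <- parse_ratio(init_ratio)
  structure(
    list(
      n_replicates = as.integer(n_replicates),
      n_passages = as.integer(n_passages),
      gated_cells = as.integer(gated_cells),
      init_ratio = init_ratio,
      init_fraction_r = frac,
      rng_seed = rng_seed
    ),
    class = "flow_design"
  )
}

parse_ratio <- function(x) {
  parts <- suppressWarnings(as.numeric(strsplit(x, ":", fixed = TRUE)[[1L]]))
  if (length(parts) != 2L || anyNA(parts) || any(parts < 0) ||
      sum(parts) == 0) {
    stop(sprintf("cannot parse ratio '%s'", x), call. = FALSE)
  }
  parts[1L] / sum(parts)
}

#' Default phenotype parameters for the well-scale flow regime
#'
#' Life histories for emulating measured co-culture wells: same rates
#' and turnover as [default_passage_phenotypes()] but a milder carrying
#' capacity enhancement in the K type (70% vs 30% of the joint capacity).
#' Under the fitted interaction strength this makes the r fraction
#' decline to extinction over roughly half a dozen passages — a
#' multi-passage decline like the measured trajectories — rather than
#' collapsing within one or two.
#'
#' @param capacity_total Joint carrying-capacity scale in cells
#'   (default 1e6, a culture well).
#' @return A list with elements `r` and `K`, both `phenotype_params`.
#' @export
default_flow_phenotypes <- function(capacity_total = 1e6) {
  stopifnot(capacity_total > 0)
  list(
    r = phenotype_params("r",
      intrinsic_rate = 0.04,
      carrying_capacity = 0.3 * capacity_total,
      baseline_death = 0.02
    ),
    K = phenotype_params("K",
      intrinsic_rate = 0.03,
      carrying_capacity = 0.7 * capacity_total,
      baseline_death = 0.02
    )
  )
}

#' Default simulator configuration for flow-style data generation
#'
#' Well-scale populations (seed 1e5 cells, joint capacity 1e6, the scale
#' of a ~1e6-cell culture well) so that measurement error is dominated by
#' binomial gating noise rather than demographic noise.
#'
#' @param design A [flow_design()].
#' @return A [passage_config()].
#' @export
flow_sim_config <- function(design) {
  stopifnot(inherits(design, "flow_design"))
  passage_config(
    n_passages = design$n_passages,
    seed_size = 1e5,
    capacity_total = 1e6,
    dt = 0.5,
    init_fraction_r = design$init_fraction_r,
    n_replicates = design$n_replicates,
    rng_seed = design$rng_seed
  )
}

#' Generate synthetic flow-cytometry fraction measurements
#'
#' Runs the stochastic serial-passage simulator per replicate and
#' overlays binomial counting noise: at each passage, the measured
#' fraction is `Binomial(gated_cells, latent fraction) / gated_cells`.
#' The latent fraction of a fully extinct culture is recorded as 0.
#'
#' @param pr,pk [phenotype_params()] for the r and K types; the
#'   well-scale defaults are [default_flow_phenotypes()].
#' @param inter [interaction_params()].
#' @param design A [flow_design()].
#' @param sim_config Optional [passage_config()] overriding
#'   [flow_sim_config()].
#' @return An `observed_dataset` (`replicate`, `passage`, `fraction_r`)
#'   with the latent fractions in column `latent_fraction_r` and the
#'   design in attribute `design`.
#' @examples
#' phen <- default_passage_phenotypes(1e5)
#' d <- gen_flow_fractions(phen$r, phen$K, interaction_params(2.2, 0),
#'                         flow_design(n_passages = 5, rng_seed = 1))
#' head(d)
#' @export
gen_flow_fractions <- function(pr, pk, inter, design,
                               sim_config = NULL) {
  stopifnot(inherits(design, "flow_design"))
  if (is.null(sim_config)) sim_config <- flow_sim_config(design)
  res <- simulate_passages(pr, pk, inter, sim_config)
  latent <- ifelse(is.na(res$fraction_r), 0, res$fraction_r)
  measured <- stats::rbinom(length(latent), design$gated_cells, latent) /
    design$gated_cells
  out <- data.frame(
    replicate = res$replicate,
    passage = res$passage,
    fraction_r = measured,
    latent_fraction_r = latent
  )
  attr(out, "design") <- design
  as_observed_dataset(out)
}

#' Reference synthetic dataset in the style of a 30-passage co-culture
#'
#' A versioned stand-in for a measured high-density co-culture fraction
#' trajectory: 9:1 initial r:K ratio, 3 replicates, 30 passages,
#' interaction coefficients alpha = 2.2, beta = 0, binomial gating of
#' 1e4 cells, generated from a fixed documented seed (20200605). The
#' same dataset ships as `inst/extdata/fig4d_synthetic.csv`; this
#' function regenerates it bit-identically. It is synthetic — generated
#' by this package, not measured.
#'
#' @param rng_seed Root seed (default 20200605, the documented fixture
#'   seed).
#' @return An `observed_dataset`.
#' @export
gen_reference_fig4d <- function(rng_seed = 20200605) {
  phen <- default_flow_phenotypes()
  design <- flow_design(
    n_replicates = 3, n_passages = 30, gated_cells = 1e4,
    init_ratio = "9:1", rng_seed = rng_seed
  )
  gen_flow_fractions(phen$r, phen$K, interaction_params(2.2, 0), design)
}

#' Path to the shipped synthetic reference dataset
#'
#' @return File path of `fig4d_synthetic.csv` inside the installed
#'   package.
#' @export
reference_fig4d_path <- function() {
  system.file("extdata", "fig4d_synthetic.csv", package = "rkcompete",
              mustWork = TRUE)
}
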