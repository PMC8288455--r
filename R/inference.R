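#' Read a fraction-vs-passage dataset
#'
#' Tabular text with header `replicate,passage,fraction_r`.
#'
#' @param path CSV file path.
#' @return A data frame of class `observed_dataset`.
#' @export
read_fraction_data <- function(path) {
  d <- utils::read.csv(path)
  as_observed_dataset(d)
}

#' Validate a fraction-vs-passage data frame
#'
#' @param d Data frame with columns `replicate`, `passage`, `fraction_r`.
#' @return `d` with class `observed_dataset`.
#' @export
as_observed_dataset <- function(d) {
  stopifnot(all(c("replicate", "passage", "fraction_r") %in% names(d)))
  if (any(d$fraction_r < 0 | d$fraction_r > 1, na.rm = TRUE)) {
    stop("fraction_r outside [0, 1]", call. = FALSE)
  }
  if (any(d$passage < 0 | d$passage != round(d$passage))) {
    stop("passage indices must be non-negative integers", call. = FALSE)
  }
  class(d) <- unique(c("observed_dataset", class(d)))
  d
}

#' Write a fraction-vs-passage dataset
#'
#' @param d Data frame with columns `replicate`, `passage`, `fraction_r`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fraction_data <- function(d, path) {
  stopifnot(all(c("replicate", "passage", "fraction_r") %in% names(d)))
  utils::write.csv(d[, c("replicate", "passage", "fraction_r")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean-squared deviation between simulated and observed fractions
#'
#' Sum over observed records of the squared deviation between the record's
#' fraction and the simulated mean fraction at that passage, divided by
#' the number of records.
#'
#' @param simulated_mean Data frame (`passage`, `fraction_r`) of simulated
#'   mean fractions, covering every observed passage.
#' @param observed An `observed_dataset` (or data frame with `passage`,
#'   `fraction_r`).
#' @return Non-negative mean squared error.
#' @export
trajectory_loss <- function(simulated_mean, observed) {
  stopifnot(all(c("passage", "fraction_r") %in% names(simulated_mean)),
            all(c("passage", "fraction_r") %in% names(observed)))
  idx <- match(observed$passage, simulated_mean$passage)
  if (anyNA(idx)) {
    missing <- unique(observed$passage[is.na(idx)])
    stop(sprintf("simulation does not cover observed passage(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  mean((observed$fraction_r - simulated_mean$fraction_r[idx])^2)
}

#' Simulated mean fraction trajectories over an interaction grid
#'
#' Computes, for every (alpha, beta) grid point, the mean r-fraction per
#' passage under the given simulator configuration. In `"ode"` mode the
#' mean is the deterministic mean-field trajectory
#' ([simulate_passages_ode()]); in `"stochastic"` mode it is the mean of
#' `n_sim` stochastic replicates run with common random numbers (the same
#' `rng_seed`) at every grid point, so that grid points differ only
#' through the parameters.
#'
#' Precomputing this table once and passing it to [fit_interactions()]
#' lets many datasets measured under the same design be fitted without
#' re-simulating.
#'
#' @param alpha_grid,beta_grid Numeric vectors of candidate coefficients.
#' @param pr,pk [phenotype_params()] for the r and K types.
#' @param config A [passage_config()] matching the observed design.
#' @param mode `"ode"` (default) or `"stochastic"`.
#' @param n_sim Stochastic replicates per grid point (stochastic mode).
#' @param rng_seed Seed shared across grid points (stochastic mode).
#' @return An object of class `grid_trajectories`: list with `grid`
#'   (data frame `alpha`, `beta`), `fractions` (matrix, one row per grid
#'   point, one column per passage 0..n_passages), and the settings.
#' @export
grid_trajectories <- function(alpha_grid, beta_grid, pr, pk, config,
                              mode = c("ode", "stochastic"),
                              n_sim = 200, rng_seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(alpha_grid) >= 1L, length(beta_grid) >= 1L,
            all(alpha_grid >= 0), all(beta_grid >= 0))
  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  frac <- matrix(NA_real_, nrow(grid), config$n_passages + 1L)
  for (g in seq_len(nrow(grid))) {
    inter <- interaction_params(grid$alpha[g], grid$beta[g])
    res <- tryCatch({
      if (mode == "ode") {
        simulate_passages_ode(pr, pk, inter, config)$fraction_r
      } else {
        cfg <- config
        cfg$n_replicates <- as.integer(n_sim)
        cfg$rng_seed <- rng_seed
        summarize_fractions(
          simulate_passages(pr, pk, inter, cfg)
        )$mean_fraction_r
      }
    }, error = function(e) {
      warning(sprintf("grid point alpha=%g beta=%g failed: %s",
                      grid$alpha[g], grid$beta[g], conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res) && length(res) == ncol(frac)) frac[g, ] <- res
  }
  structure(
    list(grid = grid, fractions = frac, mode = mode, config = config,
         n_sim = if (mode == "stochastic") n_sim else NA_integer_,
         rng_seed = if (mode == "stochastic") rng_seed else NA_integer_),
    class = "grid_trajectories"
  )
}

#' Estimate the competition coefficients by grid search
#'
#' Fits simulated r-fraction trajectories to an observed
#' fraction-vs-passage dataset by exhaustive search over an
#' (alpha, beta) grid, minimizing the mean squared error of
#' [trajectory_loss()]. Grid points whose simulation fails (e.g. invalid
#' step probabilities) receive infinite loss with a warning. Ties are
#' broken toward smaller alpha + beta, then smaller alpha (parsimony).
#'
#' @param observed An `observed_dataset`.
#' @param alpha_grid,beta_grid Candidate coefficient vectors; defaults
#'   alpha 0..4 and beta 0..2, both in steps of 0.1.
#' @inheritParams grid_trajectories
#' @param trajectories Optional precomputed [grid_trajectories()] for the
#'   same design; when supplied, no simulation is run here.
#' @return An object of class `rk_fit`: list with `alpha_hat`,
#'   `beta_hat`, `loss` (at the optimum), `surface` (data frame `alpha`,
#'   `beta`, `loss`), and `settings`.
#' @examples
#' phen <- default_passage_phenotypes(1e5)
#' cfg <- passage_config(n_passages = 10, seed_size = 1e4,
#'                       capacity_total = 1e5, n_replicates = 1)
#' truth <- simulate_passages_ode(phen$r, phen$K,
#'                                interaction_params(1, 0.5), cfg)
#' obs <- as_observed_dataset(data.frame(replicate = 1,
#'   passage = truth$passage, fraction_r = truth$fraction_r))
#' fit <- fit_interactions(obs, alpha_grid = seq(0, 2, 0.5),
#'                         beta_grid = c(0, 0.5, 1),
#'                         pr = phen$r, pk = phen$K, config = cfg)
#' c(fit$alpha_hat, fit$beta_hat)
#' @export
fit_interactions <- function(observed,
                             alpha_grid = seq(0, 4, by = 0.1),
                             beta_grid = seq(0, 2, by = 0.1),
                             pr, pk, config,
                             mode = c("ode", "stochastic"),
                             n_sim = 200, rng_seed = 1,
                             trajectories = NULL) {
  mode <- match.arg(mode)
  observed <- as_observed_dataset(observed)
  if (is.null(trajectories)) {
    trajectories <- grid_trajectories(alpha_grid, beta_grid, pr, pk,
                                      config, mode, n_sim, rng_seed)
  } else {
    stopifnot(inherits(trajectories, "grid_trajectories"))
  }
  grid <- trajectories$grid
  passages <- 0:(ncol(trajectories$fractions) - 1L)
  loss <- vapply(seq_len(nrow(grid)), function(g) {
    fr <- trajectories$fractions[g, ]
    if (anyNA(fr)) return(Inf)
    trajectory_loss(data.frame(passage = passages, fraction_r = fr),
                    observed)
  }, numeric(1L))
  best <- which(loss == min(loss))
  if (length(best) > 1L) {
    ord <- order(grid$alpha[best] + grid$beta[best], grid$alpha[best])
    best <- best[ord[1L]]
  }
  structure(
    list(
      alpha_hat = grid$alpha[best],
      beta_hat = grid$beta[best],
      loss = loss[best],
      surface = data.frame(alpha = grid$alpha, beta = grid$beta,
                           loss = loss),
      settings = list(mode = trajectories$mode,
                      config = trajectories$config,
                      n_sim = trajectories$n_sim,
                      rng_seed = trajectories$rng_seed)
    ),
    class = "rk_fit"
  )
}

#' @export
print.rk_fit <- function(x, ...) {
  cat(sprintf(
    "<rk_fit> alpha_hat=%g beta_hat=%g loss=%.4g (%s mode, %d grid points)\n",
    x$alpha_hat, x$beta_hat, x$loss, x$settings$mode, nrow(x$surface)
  ))
  invisible(x)
}

#' Write a fitted loss surface as tabular text
#'
#' @param fit An `rk_fit`.
#' @param path Output CSV path (`alpha,beta,loss`).
#' @return `path`, invisibly.
#' @export
write_loss_surface <- function(fit, path) {
  stopifnot(inherits(fit, "rk_fit"))
  utils::write.csv(fit$surface, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
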