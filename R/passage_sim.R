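#' Serial-passage simulation settings
#'
#' Configuration for the stochastic birth-death serial-passage simulator.
#' Defaults describe a desk-scale high-density passaging regime: 30
#' passages of 48 h, reseeding 10% of the joint capacity each passage.
#'
#' @param n_passages Number of passages (default 30).
#' @param passage_duration Hours per passage (default 48).
#' @param dt Hours per stochastic step (default 1); must divide
#'   `passage_duration`.
#' @param seed_size Cells reseeded at each passage (default 100).
#' @param capacity_total Joint carrying-capacity scale for the
#'   high-density condition (default 1000); used by
#'   [default_passage_phenotypes()] and for validation.
#' @param init_fraction_r Initial proportion of r cells in `[0, 1]`.
#' @param n_replicates Number of stochastic replicates (default 100).
#' @param rng_seed Integer root seed, or `NULL` to use the current RNG
#'   state. All replicates advance in lock-step from this single seeded
#'   stream (one binomial draw per event type per step across
#'   replicates), so a run is reproducible as a whole.
#' @param record_within Record every within-passage step (default FALSE;
#'   passage boundaries are always recorded).
#'
#' @return An object of class `passage_config`.
#' @export
passage_config <- function(n_passages = 30,
                           passage_duration = 48,
                           dt = 1,
                           seed_size = 100,
                           capacity_total = 1000,
                           init_fraction_r = 0.9,
                           n_replicates = 100,
                           rng_seed = NULL,
                           record_within = FALSE) {
  stopifnot(
    n_passages >= 1, passage_duration >= 0, dt > 0,
    seed_size >= 1, capacity_total > 0,
    init_fraction_r >= 0, init_fraction_r <= 1,
    n_replicates >= 1
  )
  n_steps <- passage_duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("dt must divide passage_duration", call. = FALSE)
  }
  structure(
    list(
      n_passages = as.integer(n_passages),
      passage_duration = passage_duration,
      dt = dt,
      seed_size = as.integer(round(seed_size)),
      capacity_total = capacity_total,
      init_fraction_r = init_fraction_r,
      n_replicates = as.integer(n_replicates),
      rng_seed = rng_seed,
      record_within = isTRUE(record_within)
    ),
    class = "passage_config"
  )
}

# Birth/death decomposition of the LV net rate: constant birth
# b = intrinsic + baseline_death, density-loaded death
# d = baseline_death + intrinsic * crowding / K, so the expected net
# change reproduces the LV rate plus baseline turnover. The density
# effect is loaded onto death, matching the observation that crowding
# kills r cells rather than merely pausing them.

#' One stochastic birth-death step
#'
#' Advances integer counts by `dt` hours. Births and deaths are drawn
#' independently per type as Binomial(n, b dt) and Binomial(n, d dt) with
#' constant per-capita birth rate `intrinsic_rate + baseline_death` and
#' density-dependent death rate `baseline_death +
#' intrinsic_rate * (n_self + gamma * n_other) / K`, where `gamma` is
#' `alpha` for r cells and `beta` for K cells. The expected net change
#' equals the deterministic [lv_rates()] increment.
#'
#' @inheritParams lv_rates
#' @param dt Step length in hours.
#' @return A [population_state()] `dt` hours later; counts floored at 0.
#' @export
step_counts <- function(state, pr, pk, inter, dt) {
  stopifnot(inherits(state, "population_state"), dt > 0)
  res <- sim_steps(as.integer(state$n_r), as.integer(state$n_K), 1L,
                   pr, pk, inter, dt)
  population_state(res$n_r[2L, 1L], res$n_K[2L, 1L], state$time + dt)
}

# Vectorised stepping kernel: advances all replicates in lock-step, one
# rbinom call per event type per step. Records the state after every step
# as (n_steps + 1) x n_rep matrices, first row the input state.
sim_steps <- function(n_r, n_K, n_steps, pr, pk, inter, dt) {
  br <- (pr$intrinsic_rate + pr$baseline_death) * dt
  bk <- (pk$intrinsic_rate + pk$baseline_death) * dt
  n_rep <- length(n_r)
  out_r <- matrix(0L, n_steps + 1L, n_rep)
  out_k <- matrix(0L, n_steps + 1L, n_rep)
  out_r[1L, ] <- n_r
  out_k[1L, ] <- n_K
  for (i in seq_len(n_steps)) {
    d_r <- (pr$baseline_death + pr$intrinsic_rate *
              (n_r + inter$alpha * n_K) / pr$carrying_capacity) * dt
    d_k <- (pk$baseline_death + pk$intrinsic_rate *
              (n_K + inter$beta * n_r) / pk$carrying_capacity) * dt
    if (any((br > 1 | d_r > 1) & n_r > 0L)) {
      stop(sprintf(
        "event probability for type 'r' outside [0, 1] at dt = %g h; reduce dt",
        dt), call. = FALSE)
    }
    if (any((bk > 1 | d_k > 1) & n_K > 0L)) {
      stop(sprintf(
        "event probability for type 'K' outside [0, 1] at dt = %g h; reduce dt",
        dt), call. = FALSE)
    }
    n_r <- pmax(n_r + stats::rbinom(n_rep, n_r, min(br, 1)) -
                  stats::rbinom(n_rep, n_r, pmin(d_r, 1)), 0L)
    n_K <- pmax(n_K + stats::rbinom(n_rep, n_K, min(bk, 1)) -
                  stats::rbinom(n_rep, n_K, pmin(d_k, 1)), 0L)
    out_r[i + 1L, ] <- n_r
    out_k[i + 1L, ] <- n_K
  }
  list(n_r = out_r, n_K = out_k)
}

#' Simulate one passage of growth
#'
#' Applies [step_counts()] `passage_duration / dt` times, recording every
#' step.
#'
#' @inheritParams step_counts
#' @param duration Passage length in hours.
#' @return A data frame (`time_h`, `n_r`, `n_K`), first row the initial
#'   state.
#' @export
run_passage <- function(state, pr, pk, inter, duration, dt = 1) {
  stopifnot(inherits(state, "population_state"), duration >= 0, dt > 0)
  n_steps <- as.integer(round(duration / dt))
  res <- sim_steps(as.integer(state$n_r), as.integer(state$n_K), n_steps,
                   pr, pk, inter, dt)
  data.frame(time_h = state$time + dt * (0:n_steps),
             n_r = res$n_r[, 1L], n_K = res$n_K[, 1L])
}

#' Dilute a culture to a fixed reseeding size
#'
#' Draws `seed_size` cells without replacement from the pooled population,
#' so the reseeded composition is hypergeometric and the expected
#' post-dilution fraction equals the pre-dilution fraction. If the
#' population holds fewer than `seed_size` cells, everything is reseeded
#' with a warning.
#'
#' @param state A [population_state()] with integer counts.
#' @param seed_size Number of cells to reseed (> 0).
#' @return A [population_state()] at the same time.
#' @export
dilute <- function(state, seed_size) {
  stopifnot(inherits(state, "population_state"))
  if (!is.numeric(seed_size) || seed_size <= 0) {
    stop("seed_size must be positive", call. = FALSE)
  }
  total <- state$n_r + state$n_K
  if (seed_size >= total) {
    if (seed_size > total) {
      warning("population smaller than seed_size; reseeding everything",
              call. = FALSE)
    }
    return(state)
  }
  n_r_new <- stats::rhyper(1L, m = state$n_r, n = state$n_K, k = seed_size)
  population_state(n_r_new, seed_size - n_r_new, state$time)
}

#' Stochastic serial-passage co-culture simulation
#'
#' For each replicate, seeds `round(seed_size * init_fraction_r)` r cells
#' (remainder K), then alternates within-passage birth-death growth
#' ([run_passage()]) and dilution ([dilute()]) for `n_passages` passages.
#' Pre-dilution states at every passage boundary are recorded; passage 0
#' is the seeded state.
#'
#' @param pr,pk [phenotype_params()] for the r and K types.
#' @param inter [interaction_params()].
#' @param config A [passage_config()].
#' @return An object of class `passage_result`: a data frame with columns
#'   `replicate`, `passage`, `n_r`, `n_K`, `fraction_r` (NA when the whole
#'   population is extinct), and if `record_within` is set an attribute
#'   `within`: a list with one element per passage holding the step-level
#'   count matrices (steps + 1 rows, one column per replicate). The
#'   config is echoed in attribute `config`.
#' @examples
#' phen <- default_passage_phenotypes()
#' cfg <- passage_config(n_passages = 5, n_replicates = 3, rng_seed = 1)
#' res <- simulate_passages(phen$r, phen$K, interaction_params(2.2, 0), cfg)
#' head(res)
#' @export
simulate_passages <- function(pr, pk, inter, config) {
  stopifnot(inherits(config, "passage_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  n_rep <- config$n_replicates
  n_steps <- as.integer(round(config$passage_duration / config$dt))
  # pre-dilution boundary states, one column per replicate
  bound_r <- matrix(0L, config$n_passages + 1L, n_rep)
  bound_k <- matrix(0L, config$n_passages + 1L, n_rep)
  n_r <- rep(as.integer(round(config$seed_size * config$init_fraction_r)),
             n_rep)
  n_K <- rep(config$seed_size, n_rep) - n_r
  bound_r[1L, ] <- n_r
  bound_k[1L, ] <- n_K
  within <- if (config$record_within) vector("list", config$n_passages)
  for (p in seq_len(config$n_passages)) {
    res <- sim_steps(n_r, n_K, n_steps, pr, pk, inter, config$dt)
    n_r <- res$n_r[n_steps + 1L, ]
    n_K <- res$n_K[n_steps + 1L, ]
    bound_r[p + 1L, ] <- n_r
    bound_k[p + 1L, ] <- n_K
    if (config$record_within) within[[p]] <- res
    # hypergeometric dilution wherever the population exceeds seed_size
    total <- n_r + n_K
    over <- total > config$seed_size
    if (any(over)) {
      keep_r <- stats::rhyper(sum(over), m = n_r[over], n = n_K[over],
                              k = config$seed_size)
      n_K[over] <- config$seed_size - keep_r
      n_r[over] <- keep_r
    }
  }
  rows_per_rep <- config$n_passages + 1L
  out <- data.frame(
    replicate = rep(seq_len(n_rep), each = rows_per_rep),
    passage = rep(0:config$n_passages, times = n_rep),
    n_r = as.numeric(bound_r[cbind(
      rep(seq_len(rows_per_rep), n_rep),
      rep(seq_len(n_rep), each = rows_per_rep))]),
    n_K = as.numeric(bound_k[cbind(
      rep(seq_len(rows_per_rep), n_rep),
      rep(seq_len(n_rep), each = rows_per_rep))])
  )
  total <- out$n_r + out$n_K
  out$fraction_r <- ifelse(total > 0, out$n_r / total, NA_real_)
  structure(out, config = config, within = within,
            class = c("passage_result", "data.frame"))
}

# Bare fixed-step RK4 for one within-passage integration. Same classical
# scheme as integrate_lv but without per-call solver setup, which matters
# when the grid search evaluates tens of thousands of passages; agreement
# with integrate_lv is asserted in the test suite.
lv_rk4_kernel <- function(n_r, n_K, pr, pk, inter, duration, h) {
  rr <- pr$intrinsic_rate; Kr <- pr$carrying_capacity
  rk <- pk$intrinsic_rate; Kk <- pk$carrying_capacity
  a <- inter$alpha; b <- inter$beta
  f <- function(x, y) {
    c(rr * x * (1 - (x + a * y) / Kr),
      rk * y * (1 - (y + b * x) / Kk))
  }
  n_steps <- ceiling(duration / h - 1e-9)
  for (i in seq_len(n_steps)) {
    hh <- min(h, duration - (i - 1) * h)
    k1 <- f(n_r, n_K)
    k2 <- f(n_r + hh / 2 * k1[1], n_K + hh / 2 * k1[2])
    k3 <- f(n_r + hh / 2 * k2[1], n_K + hh / 2 * k2[2])
    k4 <- f(n_r + hh * k3[1], n_K + hh * k3[2])
    n_r <- max(n_r + hh / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]), 0)
    n_K <- max(n_K + hh / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]), 0)
  }
  c(n_r, n_K)
}

#' Deterministic (mean-field) serial-passage trajectory
#'
#' Replaces the stochastic within-passage dynamics with the
#' Lotka-Volterra ODE ([integrate_lv()]) and the stochastic dilution with
#' exact proportional rescaling to `seed_size`. Used as the fast
#' deterministic mode of [fit_interactions()] and as the mean-field
#' oracle for the stochastic simulator.
#'
#' @inheritParams simulate_passages
#' @param step Integration step in hours (default 0.1).
#' @return A data frame (`passage`, `n_r`, `n_K`, `fraction_r`), passage 0
#'   being the seeded state.
#' @export
simulate_passages_ode <- function(pr, pk, inter, config, step = 0.1) {
  stopifnot(inherits(config, "passage_config"))
  n_r <- config$seed_size * config$init_fraction_r
  n_K <- config$seed_size - n_r
  out_r <- numeric(config$n_passages + 1L)
  out_k <- numeric(config$n_passages + 1L)
  out_r[1L] <- n_r
  out_k[1L] <- n_K
  for (p in seq_len(config$n_passages)) {
    end <- lv_rk4_kernel(n_r, n_K, pr, pk, inter,
                         config$passage_duration, step)
    n_r <- end[1L]
    n_K <- end[2L]
    out_r[p + 1L] <- n_r
    out_k[p + 1L] <- n_K
    total <- n_r + n_K
    if (total > config$seed_size) {
      scale <- config$seed_size / total
      n_r <- n_r * scale
      n_K <- n_K * scale
    }
  }
  total <- out_r + out_k
  data.frame(
    passage = 0:config$n_passages, n_r = out_r, n_K = out_k,
    fraction_r = ifelse(total > 0, out_r / total, NA_real_)
  )
}

#' Extinction passage of the r population
#'
#' First passage (pre-dilution) at which the r count is zero, per
#' replicate; replicates whose r population never dies out are censored
#' at `n_passages` and flagged.
#'
#' @param result A `passage_result` from [simulate_passages()].
#' @return A data frame (`replicate`, `extinction_passage`, `censored`);
#'   `extinction_passage` is NA where `censored` is TRUE.
#' @export
extinction_passage <- function(result) {
  stopifnot(inherits(result, "passage_result"))
  reps <- unique(result$replicate)
  ext <- vapply(reps, function(r) {
    sub <- result[result$replicate == r, ]
    hit <- which(sub$n_r == 0)
    if (length(hit)) sub$passage[hit[1L]] else NA_integer_
  }, integer(1L))
  data.frame(
    replicate = reps,
    extinction_passage = ext,
    censored = is.na(ext)
  )
}

#' Median extinction passage with explicit censoring value
#'
#' Censored replicates are scored one passage beyond the horizon so that
#' "never went extinct within the experiment" ranks above every observed
#' extinction; the median is then taken over all replicates.
#'
#' @param ext Output of [extinction_passage()].
#' @param horizon Number of passages simulated; defaults to the largest
#'   observed value.
#' @return The median, a single number.
#' @export
median_extinction <- function(ext, horizon = NULL) {
  stopifnot(all(c("extinction_passage", "censored") %in% names(ext)))
  if (is.null(horizon)) {
    horizon <- max(ext$extinction_passage, 0, na.rm = TRUE)
  }
  x <- ext$extinction_passage
  x[ext$censored] <- horizon + 1
  stats::median(x)
}

#' Per-passage mean and SD of the r-cell fraction
#'
#' Summary matching the mean-plus-minus-SD presentation of fraction
#' trajectories: extinct-whole-population records are dropped per passage.
#'
#' @param result A `passage_result` (or any data frame with `passage` and
#'   `fraction_r`).
#' @return A data frame (`passage`, `mean_fraction_r`, `sd_fraction_r`,
#'   `n`).
#' @export
summarize_fractions <- function(result) {
  stopifnot(all(c("passage", "fraction_r") %in% names(result)))
  ok <- !is.na(result$fraction_r)
  agg <- split(result$fraction_r[ok], result$passage[ok])
  data.frame(
    passage = as.integer(names(agg)),
    mean_fraction_r = vapply(agg, mean, numeric(1L)),
    sd_fraction_r = vapply(agg, stats::sd, numeric(1L)),
    n = vapply(agg, length, integer(1L)),
    row.names = NULL
  )
}
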