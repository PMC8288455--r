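#' Lotka-Volterra competition rates
#'
#' Net per-hour rates of change of the two populations under the standard
#' two-type competitive Lotka-Volterra model,
#' \deqn{dn_r/dt = r_r n_r (1 - (n_r + \alpha n_K)/K_r)}
#' \deqn{dn_K/dt = r_K n_K (1 - (n_K + \beta n_r)/K_K)}
#' where `alpha` weights the crowding effect of K cells on r cells and
#' `beta` the reverse.
#'
#' @param state A [population_state()].
#' @param pr,pk [phenotype_params()] for the r and K types.
#' @param inter [interaction_params()].
#'
#' @return Named numeric vector `c(dn_r, dn_K)` in cells per hour. A type
#'   with zero count has rate exactly 0 (extinction is absorbing).
#' @examples
#' st <- population_state(n_r = 10, n_K = 20)
#' pr <- phenotype_params("r", 0.9, 100)
#' pk <- phenotype_params("K", 0.3, 100)
#' lv_rates(st, pr, pk, interaction_params(alpha = 2.2, beta = 0))
#' @export
lv_rates <- function(state, pr, pk, inter) {
  stopifnot(inherits(state, "population_state"),
            inherits(pr, "phenotype_params"),
            inherits(pk, "phenotype_params"),
            inherits(inter, "interaction_params"))
  n_r <- state$n_r
  n_K <- state$n_K
  dn_r <- pr$intrinsic_rate * n_r *
    (1 - (n_r + inter$alpha * n_K) / pr$carrying_capacity)
  dn_K <- pk$intrinsic_rate * n_K *
    (1 - (n_K + inter$beta * n_r) / pk$carrying_capacity)
  c(dn_r = dn_r, dn_K = dn_K)
}

#' Closed-form logistic growth
#'
#' Analytic solution of dn/dt = r n (1 - n/K):
#' n(t) = K / (1 + (K/n0 - 1) exp(-r t)). Serves as the exact oracle for
#' the numerical integrator in the decoupled (alpha = beta = 0) limit.
#'
#' @param n0 Initial count (> 0).
#' @param r Per-hour intrinsic rate.
#' @param K Carrying capacity (> 0).
#' @param t Time in hours (vectorised).
#'
#' @return Population size at each `t`.
#' @export
logistic_closed_form <- function(n0, r, K, t) {
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) || n0 <= 0) {
    stop("n0 must be a single positive number", call. = FALSE)
  }
  stopifnot(K > 0, is.numeric(r), is.numeric(t))
  K / (1 + (K / n0 - 1) * exp(-r * t))
}

# Derivative callback for deSolve; counts floored at 0 so that a tiny
# numerical undershoot cannot feed back into the dynamics and extinction
# stays absorbing.
lv_deriv <- function(t, y, parms) {
  n_r <- max(y[[1L]], 0)
  n_K <- max(y[[2L]], 0)
  dn_r <- parms$rr * n_r * (1 - (n_r + parms$alpha * n_K) / parms$Kr)
  dn_K <- parms$rk * n_K * (1 - (n_K + parms$beta * n_r) / parms$Kk)
  list(c(dn_r, dn_K))
}

#' Integrate the Lotka-Volterra competition model
#'
#' Deterministic trajectory by fixed-step classical 4th-order Runge-Kutta
#' (via [deSolve::ode()]). Fixed stepping keeps trajectories reproducible
#' bit-for-bit across platforms given identical settings. Counts that
#' undershoot 0 are clamped to 0 with a warning.
#'
#' @param state0 Initial [population_state()]; its `time` must equal the
#'   first element of `t_grid`.
#' @param pr,pk [phenotype_params()] for the r and K types.
#' @param inter [interaction_params()].
#' @param t_grid Strictly increasing vector of output times in hours.
#' @param step Integration step in hours (default 0.1).
#'
#' @return A data frame of class `lv_trajectory` with columns `time_h`,
#'   `n_r`, `n_K`, and the parameters in attribute `settings`.
#' @examples
#' pr <- phenotype_params("r", 0.04, 100)
#' pk <- phenotype_params("K", 0.025, 900)
#' traj <- integrate_lv(population_state(10, 90), pr, pk,
#'                      interaction_params(2.2, 0), t_grid = 0:48)
#' tail(traj, 3)
#' @export
integrate_lv <- function(state0, pr, pk, inter, t_grid, step = 0.1) {
  stopifnot(inherits(state0, "population_state"),
            is.numeric(t_grid), length(t_grid) >= 1L,
            all(diff(t_grid) > 0), step > 0)
  if (abs(t_grid[1L] - state0$time) > 1e-9) {
    stop("t_grid must start at state0$time", call. = FALSE)
  }
  parms <- list(
    rr = pr$intrinsic_rate, Kr = pr$carrying_capacity,
    rk = pk$intrinsic_rate, Kk = pk$carrying_capacity,
    alpha = inter$alpha, beta = inter$beta
  )
  t0 <- t_grid[1L]
  tmax <- t_grid[length(t_grid)]
  times <- sort(unique(c(seq(t0, tmax, by = step), t_grid, tmax)))
  sol <- deSolve::ode(
    y = c(n_r = state0$n_r, n_K = state0$n_K),
    times = times, func = lv_deriv, parms = parms, method = "rk4"
  )
  if (any(!is.finite(sol[, c("n_r", "n_K")]))) {
    stop(sprintf("integration produced non-finite values at step %g h", step),
         call. = FALSE)
  }
  keep <- match_times(times, t_grid)
  out <- data.frame(
    time_h = t_grid,
    n_r = sol[keep, "n_r"],
    n_K = sol[keep, "n_K"]
  )
  if (any(out$n_r < 0) || any(out$n_K < 0)) {
    warning("integration undershot 0; counts clamped", call. = FALSE)
    out$n_r <- pmax(out$n_r, 0)
    out$n_K <- pmax(out$n_K, 0)
  }
  structure(out,
            settings = list(pr = pr, pk = pk, inter = inter, step = step),
            class = c("lv_trajectory", "data.frame"))
}

# Index of each requested output time inside the integration grid,
# tolerant to floating-point drift from seq().
match_times <- function(times, t_grid) {
  idx <- findInterval(t_grid + 1e-9, times)
  if (any(abs(times[idx] - t_grid) > 1e-6)) {
    stop("internal error: output time missing from integration grid")
  }
  idx
}

#' Classify the long-run outcome of two-type competition
#'
#' Standard invasion analysis of the competitive Lotka-Volterra model:
#' r invades K's single-type equilibrium iff alpha < K_r/K_K, and K
#' invades r's equilibrium iff beta < K_K/K_r. Both criteria satisfied
#' gives stable coexistence, neither gives founder-controlled bistability,
#' and exactly one gives competitive exclusion of the non-invader.
#'
#' @inheritParams lv_rates
#' @return One of `"coexistence"`, `"bistable"`, `"r_excluded"`,
#'   `"K_excluded"`.
#' @examples
#' pr <- phenotype_params("r", 0.04, 100); pk <- phenotype_params("K", 0.025, 100)
#' classify_outcome(pr, pk, interaction_params(2.2, 0)) # "r_excluded"
#' @export
classify_outcome <- function(pr, pk, inter) {
  stopifnot(inherits(pr, "phenotype_params"),
            inherits(pk, "phenotype_params"),
            inherits(inter, "interaction_params"))
  r_invades <- inter$alpha < pr$carrying_capacity / pk$carrying_capacity
  k_invades <- inter$beta < pk$carrying_capacity / pr$carrying_capacity
  if (r_invades && k_invades) return("coexistence")
  if (!r_invades && !k_invades) return("bistable")
  if (r_invades) "K_excluded" else "r_excluded"
}

#' Write a trajectory as tidy tabular text
#'
#' @param traj An `lv_trajectory` (or any data frame with columns
#'   `time_h`, `n_r`, `n_K`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(all(c("time_h", "n_r", "n_K") %in% names(traj)))
  utils::write.csv(traj[, c("time_h", "n_r", "n_K")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
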