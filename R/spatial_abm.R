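#' Spatial agent-based model settings
#'
#' Configuration for the on-lattice model of r/K co-growth. Cells occupy
#' at most one site each; division and death rates depend on local
#' density in the Moore neighborhood (8 surrounding sites), and division
#' and migration require at least one empty neighboring site. The lattice
#' boundary is a reflecting wall (a culture-well edge). Defaults are a
#' desk-scale stand-in for a ~1e6-cell well: 200 x 200 sites, ~3000 cells
#' seeded well-mixed in a central disc.
#'
#' @param width,height Lattice dimensions in sites (default 200 x 200).
#' @param seeding_radius Radius in sites of the central seeding disc.
#' @param init_fraction_r Proportion of seeded cells of type r; exact
#'   counts by rounding, then shuffled placement.
#' @param total_seeded Number of cells seeded (must fit in the disc).
#' @param dt Hours per sweep (default 1, the growth-rate measurement
#'   interval).
#' @param horizon Simulated hours (default 144, i.e. six days).
#' @param snapshot_times Hours at which full lattice snapshots are kept.
#' @param n_replicates Number of stochastic replicates (default 100).
#' @param rng_seed Integer root seed or `NULL`; per-replicate streams are
#'   spawned as in [passage_config()].
#'
#' @return An object of class `spatial_config`.
#' @export
spatial_config <- function(width = 200, height = 200,
                           seeding_radius = 32,
                           init_fraction_r = 0.5,
                           total_seeded = 3000,
                           dt = 1,
                           horizon = 144,
                           snapshot_times = c(72, 144),
                           n_replicates = 100,
                           rng_seed = NULL) {
  stopifnot(
    width >= 3, height >= 3, seeding_radius >= 1,
    init_fraction_r >= 0, init_fraction_r <= 1,
    total_seeded >= 1, dt > 0, horizon >= 0,
    n_replicates >= 1
  )
  snapshot_times <- sort(unique(snapshot_times))
  if (length(snapshot_times) && any(snapshot_times > horizon)) {
    stop("snapshot_times must not exceed horizon", call. = FALSE)
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      seeding_radius = seeding_radius,
      init_fraction_r = init_fraction_r,
      total_seeded = as.integer(total_seeded),
      dt = dt, horizon = horizon,
      snapshot_times = snapshot_times,
      n_replicates = as.integer(n_replicates),
      rng_seed = rng_seed
    ),
    class = "spatial_config"
  )
}

lattice_center <- function(lattice) {
  c((nrow(lattice) + 1) / 2, (ncol(lattice) + 1) / 2)
}

#' Seed a lattice with a well-mixed central colony
#'
#' Places `total_seeded` cells on sites drawn uniformly without
#' replacement from the disc of `seeding_radius` around the lattice
#' center. Exactly `round(total_seeded * init_fraction_r)` cells are type
#' r (rest K), assigned to the chosen sites in shuffled order.
#'
#' @param config A [spatial_config()].
#' @return An integer matrix of class `rk_lattice` (0 empty, 1 r, 2 K)
#'   with attribute `time` = 0.
#' @export
seed_lattice <- function(config) {
  stopifnot(inherits(config, "spatial_config"))
  occ <- matrix(0L, nrow = config$height, ncol = config$width)
  ctr <- lattice_center(occ)
  rows <- rep(seq_len(config$height), times = config$width)
  cols <- rep(seq_len(config$width), each = config$height)
  in_disc <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= config$seeding_radius^2
  disc <- which(in_disc)
  if (length(disc) < config$total_seeded) {
    stop(sprintf(
      "seeding disc holds %d sites but total_seeded is %d",
      length(disc), config$total_seeded
    ), call. = FALSE)
  }
  sites <- sample(disc, config$total_seeded)
  n_r <- as.integer(round(config$total_seeded * config$init_fraction_r))
  types <- sample(rep(c(1L, 2L), c(n_r, config$total_seeded - n_r)))
  occ[sites] <- types
  structure(occ, time = 0, class = c("rk_lattice", class(occ)))
}

#' Local crowding felt by a cell
#'
#' For an r cell at `site`: (r neighbors + alpha * K neighbors) / 8; for
#' a K cell, (K neighbors + beta * r neighbors) / 8. The denominator is
#' always 8; wall sites beyond the boundary contribute nothing.
#'
#' @param lattice An `rk_lattice`.
#' @param row,col Site coordinates (1-based).
#' @param inter [interaction_params()].
#' @return Crowding score, 0 for an isolated cell.
#' @export
local_crowding <- function(lattice, row, col, inter) {
  stopifnot(inherits(inter, "interaction_params"))
  if (lattice[row, col] == 0L) {
    stop("site is empty", call. = FALSE)
  }
  local_crowding_cpp(unclass(lattice), row - 1L, col - 1L,
                     inter$alpha, inter$beta)
}

#' One asynchronous sweep of the spatial model
#'
#' Cells present at the start of the sweep are visited in a fresh uniform
#' random order. Each attempts, mutually exclusively and in this order:
#' death with probability `(baseline_death + density_death_coef *
#' crowding) * dt`; if survived and an empty Moore neighbor exists,
#' division with probability `intrinsic_rate * dt`, the daughter placed
#' on a uniformly chosen empty neighbor; otherwise migration with
#' probability `motility * dt` to a uniformly chosen empty neighbor.
#' Fully enclosed cells can neither divide nor migrate.
#'
#' @param lattice An `rk_lattice`.
#' @param pr,pk [phenotype_params()] for the r and K types.
#' @param inter [interaction_params()].
#' @param dt Hours per sweep.
#' @return The updated `rk_lattice`, time advanced by `dt`.
#' @export
step_lattice <- function(lattice, pr, pk, inter, dt = 1) {
  out <- step_lattice_cpp(
    unclass(lattice), inter$alpha, inter$beta,
    pr$intrinsic_rate, pr$baseline_death, pr$density_death_coef,
    pr$motility,
    pk$intrinsic_rate, pk$baseline_death, pk$density_death_coef,
    pk$motility,
    dt
  )
  structure(out, time = attr(lattice, "time") + dt,
            class = c("rk_lattice", class(out)))
}

#' Run the spatial agent-based model
#'
#' `n_replicates` independent runs from fresh seedings; population counts
#' are recorded every sweep and full lattice snapshots kept at
#' `snapshot_times` (plus time 0).
#'
#' @inheritParams step_lattice
#' @param config A [spatial_config()].
#' @return An object of class `spatial_result`: list with `counts` (data
#'   frame `replicate`, `time_h`, `n_r`, `n_K`, `total`), `snapshots`
#'   (list per replicate of named lattices), and `config`.
#' @examples
#' phen <- default_spatial_phenotypes()
#' cfg <- spatial_config(width = 40, height = 40, seeding_radius = 8,
#'                       total_seeded = 100, horizon = 24,
#'                       snapshot_times = 24, n_replicates = 2, rng_seed = 1)
#' res <- run_spatial(phen$r, phen$K, interaction_params(2.2, 0), cfg)
#' head(res$counts)
#' @export
run_spatial <- function(pr, pk, inter, config) {
  stopifnot(inherits(config, "spatial_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  n_steps <- as.integer(round(config$horizon / config$dt))
  times <- config$dt * (0:n_steps)
  snap_steps <- vapply(
    config$snapshot_times,
    function(t) which.min(abs(times - t)) - 1L, integer(1L)
  )
  counts <- vector("list", config$n_replicates)
  snapshots <- vector("list", config$n_replicates)
  for (rep_i in seq_len(config$n_replicates)) {
    set.seed(sub_seeds[rep_i])
    lat <- seed_lattice(config)
    n_r <- integer(n_steps + 1L)
    n_K <- integer(n_steps + 1L)
    ct <- count_types_cpp(unclass(lat))
    n_r[1L] <- ct[["n_r"]]
    n_K[1L] <- ct[["n_K"]]
    snaps <- list(`0` = lat)
    for (s in seq_len(n_steps)) {
      lat <- step_lattice(lat, pr, pk, inter, config$dt)
      ct <- count_types_cpp(unclass(lat))
      n_r[s + 1L] <- ct[["n_r"]]
      n_K[s + 1L] <- ct[["n_K"]]
      if (s %in% snap_steps) snaps[[as.character(times[s + 1L])]] <- lat
    }
    counts[[rep_i]] <- data.frame(
      replicate = rep_i, time_h = times, n_r = n_r, n_K = n_K,
      total = n_r + n_K
    )
    snapshots[[rep_i]] <- snaps
  }
  structure(
    list(counts = do.call(rbind, counts), snapshots = snapshots,
         config = config),
    class = "spatial_result"
  )
}

#' Radial segregation index of a two-type colony
#'
#' Normalized difference in mean Euclidean distance from the lattice
#' center: (mean r distance - mean K distance) / (mean all-cell
#' distance). Positive values mean r cells sit peripherally and K cells
#' centrally; 0 is expected under random labelling.
#'
#' @param lattice An `rk_lattice`.
#' @return A single number, or `NA` if either type is absent.
#' @export
segregation_index <- function(lattice) {
  occ <- unclass(lattice)
  idx <- which(occ != 0L)
  if (!length(idx)) return(NA_real_)
  types <- occ[idx]
  if (!any(types == 1L) || !any(types == 2L)) return(NA_real_)
  ctr <- lattice_center(occ)
  rows <- (idx - 1L) %% nrow(occ) + 1L
  cols <- (idx - 1L) %/% nrow(occ) + 1L
  d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  (mean(d[types == 1L]) - mean(d[types == 2L])) / mean(d)
}

#' Permutation test for radial segregation
#'
#' Re-labels the occupied sites of a lattice uniformly at random (holding
#' the type counts fixed) to build the null distribution of
#' [segregation_index()], and returns the one-sided p-value for the
#' observed index being larger than expected under random mixing.
#'
#' @param lattice An `rk_lattice` containing both types.
#' @param n_perm Number of label permutations (default 199).
#' @return List with `observed`, `p_value`, and the vector of `null`
#'   indices.
#' @export
segregation_test <- function(lattice, n_perm = 199) {
  obs <- segregation_index(lattice)
  if (is.na(obs)) stop("both types must be present", call. = FALSE)
  occ <- unclass(lattice)
  idx <- which(occ != 0L)
  types <- occ[idx]
  null <- vapply(seq_len(n_perm), function(i) {
    shuf <- occ
    shuf[idx] <- sample(types)
    segregation_index(structure(shuf, class = class(lattice)))
  }, numeric(1L))
  list(
    observed = obs,
    p_value = (1 + sum(null >= obs)) / (1 + n_perm),
    null = null
  )
}

#' Per-interval growth-rate series across replicates
#'
#' Per-capita growth rate over each recording interval,
#' (N(t + dt) - N(t)) / N(t), averaged over replicates, matching a
#' growth-rate readout taken at one-hour intervals. Intervals where a
#' replicate's population is 0 are excluded from that replicate's
#' contribution.
#'
#' @param result A `spatial_result` from [run_spatial()].
#' @return A data frame (`time_h` = interval start, `mean_rate`,
#'   `sd_rate`, `n`).
#' @export
growth_rate_series <- function(result) {
  if (!inherits(result, "spatial_result") || !nrow(result$counts)) {
    stop("result must be a non-empty spatial_result", call. = FALSE)
  }
  counts <- result$counts
  rates <- do.call(rbind, lapply(split(counts, counts$replicate), function(d) {
    d <- d[order(d$time_h), ]
    n <- nrow(d)
    if (n < 2L) return(NULL)
    data.frame(
      time_h = d$time_h[-n],
      rate = (d$total[-1L] - d$total[-n]) / d$total[-n]
    )
  }))
  rates <- rates[is.finite(rates$rate), ]
  agg <- split(rates$rate, rates$time_h)
  data.frame(
    time_h = as.numeric(names(agg)),
    mean_rate = vapply(agg, mean, numeric(1L)),
    sd_rate = vapply(agg, stats::sd, numeric(1L)),
    n = vapply(agg, length, integer(1L)),
    row.names = NULL
  )
}

#' Write a lattice snapshot as a plain-text grid
#'
#' One row of space-separated codes per lattice row: 0 empty, 1 r, 2 K.
#'
#' @param lattice An `rk_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path) {
  utils::write.table(unclass(lattice), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a lattice snapshot as a raster image
#'
#' Renders empty sites black, r cells green and K cells red (the usual
#' eGFP/dsRed display convention) into a PNG. Requires the `png`
#' package.
#'
#' @param lattice An `rk_lattice`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_lattice_image <- function(lattice, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for raster export", call. = FALSE)
  }
  occ <- unclass(lattice)
  img <- array(0, dim = c(nrow(occ), ncol(occ), 3))
  img[, , 2][occ == 1L] <- 1  # r: green
  img[, , 1][occ == 2L] <- 1  # K: red
  png::writePNG(img, path)
  invisible(path)
}

#' Read a plain-text lattice grid
#'
#' @param path File written by [write_lattice()].
#' @param time Time attribute in hours to attach (default 0).
#' @return An `rk_lattice`.
#' @export
read_lattice <- function(path, time = 0) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  structure(m, time = time, class = c("rk_lattice", class(m)))
}

#' @export
print.rk_lattice <- function(x, ...) {
  ct <- count_types_cpp(unclass(x))
  cat(sprintf("<rk_lattice %dx%d> t=%gh n_r=%d n_K=%d\n",
              nrow(x), ncol(x), attr(x, "time"),
              ct[["n_r"]], ct[["n_K"]]))
  invisible(x)
}
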