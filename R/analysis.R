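#' End-point log-linear growth rate from daily counts
#'
#' Per-day growth rate computed from first and last daily counts,
#' `(ln N_last - ln N_first) / days`, the standard seven-day summary when
#' eight daily counts (day 0 through day 7) are supplied.
#'
#' @param counts Vector of daily cell counts (>= 2 values, all > 0).
#' @return Per-day rate, a single number.
#' @examples
#' growth_rate_7day(1000 * 2^(0:7)) # doubling daily -> log(2)
#' @export
growth_rate_7day <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 2L) {
    stop("need at least two daily counts", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("counts must be positive", call. = FALSE)
  }
  n <- length(counts)
  (log(counts[n]) - log(counts[1L])) / (n - 1L)
}

#' Mean, SD and n per condition
#'
#' @param values Numeric vector of replicate measurements.
#' @param condition Grouping vector of the same length.
#' @return Data frame (`condition`, `mean`, `sd`, `n`); `sd` is the
#'   sample SD (n - 1 denominator), NA for singleton groups.
#' @examples
#' summarize_replicates(c(1, 2, 3), rep("a", 3))
#' @export
summarize_replicates <- function(values, condition) {
  if (!length(values) || length(values) != length(condition)) {
    stop("values and condition must be non-empty and equal length",
         call. = FALSE)
  }
  groups <- split(values, condition)
  if (any(!vapply(groups, length, integer(1L)))) {
    stop("every condition needs at least one value", call. = FALSE)
  }
  data.frame(
    condition = names(groups),
    mean = vapply(groups, mean, numeric(1L)),
    sd = vapply(groups, stats::sd, numeric(1L)),
    n = vapply(groups, length, integer(1L)),
    row.names = NULL
  )
}

#' Specification of a canned in-silico experiment
#'
#' @param name One of `"fig4d_fractions"` (fraction trajectories under
#'   fitted vs null interactions at several seeding ratios),
#'   `"extinction_vs_alpha"` (extinction-passage distributions over an
#'   alpha grid), `"spatial_niche"` (central co-seeding, snapshots and
#'   segregation series) or `"mixed_fitness"` (growth-rate comparison of
#'   pure r, pure K and the 1:1 mix).
#' @param out_dir Output directory (created if missing).
#' @param rng_seed Integer root seed.
#' @param n_replicates Replicates per condition (default 100).
#' @param spatial Optional [spatial_config()] override for the spatial
#'   experiments.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(name = c("fig4d_fractions",
                                     "extinction_vs_alpha",
                                     "spatial_niche",
                                     "mixed_fitness"),
                            out_dir,
                            rng_seed = 1,
                            n_replicates = 100,
                            spatial = NULL) {
  name <- match.arg(name)
  stopifnot(is.character(out_dir), length(out_dir) == 1L,
            n_replicates >= 1)
  structure(
    list(name = name, out_dir = out_dir, rng_seed = rng_seed,
         n_replicates = as.integer(n_replicates), spatial = spatial),
    class = "experiment_spec"
  )
}

write_manifest <- function(spec, extra, path) {
  manifest <- c(
    list(
      experiment = spec$name,
      rng_seed = spec$rng_seed,
      n_replicates = spec$n_replicates,
      package_version = as.character(utils::packageVersion("rkcompete"))
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Run a canned in-silico experiment
#'
#' Executes one of the four experiment drivers and writes its result
#' tables (CSV), lattice snapshots (plain-text grids) and a JSON manifest
#' recording the configuration, seed and package version to
#' `spec$out_dir`. Reruns with the same spec produce identical files.
#'
#' @param spec An [experiment_spec()].
#' @return Invisibly, a list of the in-memory results.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(spec$name,
    fig4d_fractions = run_fig4d_fractions(spec),
    extinction_vs_alpha = run_extinction_vs_alpha(spec),
    spatial_niche = run_spatial_niche(spec),
    mixed_fitness = run_mixed_fitness(spec)
  )
  invisible(res)
}

run_fig4d_fractions <- function(spec) {
  phen <- default_passage_phenotypes()
  conditions <- list(
    list(label = "alpha2.2_beta0_9to1", inter = interaction_params(2.2, 0),
         init = 0.9),
    list(label = "alpha0_beta0_9to1", inter = interaction_params(0, 0),
         init = 0.9),
    list(label = "alpha0_beta0_1to1", inter = interaction_params(0, 0),
         init = 0.5),
    list(label = "alpha0_beta0_1to9", inter = interaction_params(0, 0),
         init = 0.1)
  )
  curves <- lapply(seq_along(conditions), function(i) {
    cond <- conditions[[i]]
    cfg <- passage_config(init_fraction_r = cond$init, dt = 0.5,
                          n_replicates = spec$n_replicates,
                          rng_seed = spec$rng_seed + i)
    s <- summarize_fractions(simulate_passages(phen$r, phen$K, cond$inter,
                                               cfg))
    s$condition <- cond$label
    s
  })
  curves <- do.call(rbind, curves)
  fixture <- read_fraction_data(reference_fig4d_path())
  utils::write.csv(curves, file.path(spec$out_dir, "fraction_curves.csv"),
                   row.names = FALSE)
  write_fraction_data(fixture,
                      file.path(spec$out_dir, "reference_overlay.csv"))
  write_manifest(spec, list(conditions = vapply(conditions, `[[`,
                                                character(1L), "label")),
                 file.path(spec$out_dir, "manifest.json"))
  list(curves = curves, fixture = fixture)
}

run_extinction_vs_alpha <- function(spec, alphas = c(0, 1, 2, 3)) {
  phen <- default_passage_phenotypes()
  tabs <- lapply(seq_along(alphas), function(i) {
    cfg <- passage_config(dt = 0.5, n_replicates = spec$n_replicates,
                          rng_seed = spec$rng_seed + i)
    ext <- extinction_passage(
      simulate_passages(phen$r, phen$K, interaction_params(alphas[i], 0),
                        cfg)
    )
    ext$alpha <- alphas[i]
    ext
  })
  tab <- do.call(rbind, tabs)
  utils::write.csv(tab, file.path(spec$out_dir, "extinction_passages.csv"),
                   row.names = FALSE)
  medians <- data.frame(
    alpha = alphas,
    median_extinction = vapply(tabs, median_extinction, numeric(1L),
                               horizon = 30)
  )
  utils::write.csv(medians, file.path(spec$out_dir, "medians.csv"),
                   row.names = FALSE)
  write_manifest(spec, list(alphas = alphas),
                 file.path(spec$out_dir, "manifest.json"))
  list(extinctions = tab, medians = medians)
}

run_spatial_niche <- function(spec) {
  phen <- default_spatial_phenotypes()
  cfg <- spec$spatial
  if (is.null(cfg)) cfg <- spatial_config()
  cfg$n_replicates <- spec$n_replicates
  cfg$rng_seed <- spec$rng_seed
  res <- run_spatial(phen$r, phen$K, interaction_params(2.2, 0), cfg)
  seg <- do.call(rbind, lapply(seq_along(res$snapshots), function(i) {
    snaps <- res$snapshots[[i]]
    data.frame(
      replicate = i,
      time_h = as.numeric(names(snaps)),
      segregation_index = vapply(snaps, segregation_index, numeric(1L))
    )
  }))
  utils::write.csv(seg, file.path(spec$out_dir, "segregation.csv"),
                   row.names = FALSE)
  utils::write.csv(res$counts, file.path(spec$out_dir, "counts.csv"),
                   row.names = FALSE)
  final <- res$snapshots[[1L]]
  write_lattice(final[[length(final)]],
                file.path(spec$out_dir, "snapshot_rep1_final.txt"))
  write_manifest(spec, list(lattice = c(cfg$height, cfg$width),
                            horizon = cfg$horizon),
                 file.path(spec$out_dir, "manifest.json"))
  list(result = res, segregation = seg)
}

run_mixed_fitness <- function(spec) {
  phen <- default_spatial_phenotypes()
  # bounded-well geometry: small enough that the fast r population can
  # saturate it within the nine-day observation window, which is when the
  # complementarity of the mix shows up in the growth rate
  base <- spec$spatial
  if (is.null(base)) {
    base <- spatial_config(width = 64, height = 64, seeding_radius = 16,
                           total_seeded = 700, horizon = 216,
                           snapshot_times = numeric(0))
  }
  conditions <- list(pure_r = 1, mix = 0.5, pure_K = 0)
  series <- lapply(seq_along(conditions), function(i) {
    cfg <- base
    cfg$init_fraction_r <- conditions[[i]]
    cfg$n_replicates <- spec$n_replicates
    cfg$rng_seed <- spec$rng_seed + i
    res <- run_spatial(phen$r, phen$K, interaction_params(2.2, 0), cfg)
    gr <- growth_rate_series(res)
    gr$condition <- names(conditions)[i]
    list(rates = gr, counts = res$counts)
  })
  rates <- do.call(rbind, lapply(series, `[[`, "rates"))
  counts <- do.call(rbind, lapply(seq_along(series), function(i) {
    d <- series[[i]]$counts
    d$condition <- names(conditions)[i]
    d
  }))
  utils::write.csv(rates, file.path(spec$out_dir, "growth_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(counts, file.path(spec$out_dir, "growth_curves.csv"),
                   row.names = FALSE)
  # late-horizon comparison: per-replicate mean rate over the final
  # quarter of the run, plus Welch two-sample comparisons vs the mix
  t_late <- 0.75 * base$horizon
  per_rep <- do.call(rbind, lapply(seq_along(series), function(i) {
    d <- series[[i]]$counts
    d <- d[order(d$replicate, d$time_h), ]
    rate <- unlist(lapply(split(d, d$replicate), function(r) {
      n <- nrow(r)
      v <- (r$total[-1L] - r$total[-n]) / r$total[-n]
      mean(v[r$time_h[-n] >= t_late & is.finite(v)])
    }), use.names = FALSE)
    data.frame(condition = names(conditions)[i], rate = rate)
  }))
  cmp <- summarize_replicates(per_rep$rate, per_rep$condition)
  for (other in c("pure_r", "pure_K")) {
    tt <- stats::t.test(per_rep$rate[per_rep$condition == "mix"],
                        per_rep$rate[per_rep$condition == other])
    cmp[[paste0("p_mix_vs_", other)]] <-
      ifelse(cmp$condition == "mix", tt$p.value, NA_real_)
  }
  utils::write.csv(cmp, file.path(spec$out_dir, "late_rate_summary.csv"),
                   row.names = FALSE)
  write_manifest(spec, list(conditions = names(conditions),
                            lattice = c(base$height, base$width),
                            horizon = base$horizon),
                 file.path(spec$out_dir, "manifest.json"))
  list(rates = rates, late_summary = cmp)
}
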