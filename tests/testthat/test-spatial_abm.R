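spatial_inter <- interaction_params(2.2, 0)

test_that("seeding fills the central disc with exact type counts", {
  cfg <- spatial_config(width = 21, height = 21, seeding_radius = 5,
                        total_seeded = 40, init_fraction_r = 0.5,
                        n_replicates = 1)
  set.seed(1)
  lat <- seed_lattice(cfg)
  ct <- table(factor(unclass(lat)[unclass(lat) > 0], levels = 1:2))
  expect_equal(sum(ct), 40)
  expect_equal(unname(ct[["1"]]), 20)  # exact-count assignment at 0.5

  # all cells inside the disc
  idx <- which(unclass(lat) > 0)
  rows <- (idx - 1) %% 21 + 1
  cols <- (idx - 1) %/% 21 + 1
  expect_true(all((rows - 11)^2 + (cols - 11)^2 <= 25))

  # fraction 0: all K
  cfg0 <- spatial_config(width = 21, height = 21, seeding_radius = 5,
                         total_seeded = 10, init_fraction_r = 0)
  set.seed(2)
  expect_true(all(unclass(seed_lattice(cfg0)) %in% c(0L, 2L)))

  # full disc occupancy when total_seeded equals the disc size
  disc_size <- sum(outer((1:21) - 11, (1:21) - 11,
                         function(a, b) a^2 + b^2) <= 25)
  cfgf <- spatial_config(width = 21, height = 21, seeding_radius = 5,
                         total_seeded = disc_size)
  set.seed(3)
  latf <- seed_lattice(cfgf)
  idxf <- which(unclass(latf) > 0)
  expect_equal(length(idxf), disc_size)

  # oversized seeding is a configuration error
  expect_error(
    seed_lattice(spatial_config(width = 21, height = 21,
                                seeding_radius = 2, total_seeded = 500)),
    "disc"
  )
})

test_that("local crowding weights neighbors by the competition terms", {
  # isolated r cell
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_equal(local_crowding(toy_lattice(m), 3, 3, spatial_inter), 0)

  # r cell fully surrounded by K cells: 8 * alpha / 8 = alpha
  m2 <- matrix(2L, 3, 3); m2[2, 2] <- 1L
  expect_equal(local_crowding(toy_lattice(m2), 2, 2,
                              interaction_params(2.2, 0)), 2.2)

  # K cell fully surrounded by r cells with beta = 0: no crowding at all
  m3 <- matrix(1L, 3, 3); m3[2, 2] <- 2L
  expect_equal(local_crowding(toy_lattice(m3), 2, 2,
                              interaction_params(2.2, 0)), 0)

  # mixed neighborhood: 3 r + 2 K neighbors of an r cell
  m4 <- matrix(0L, 3, 3); m4[2, 2] <- 1L
  m4[1, 1] <- 1L; m4[1, 2] <- 1L; m4[1, 3] <- 1L
  m4[3, 1] <- 2L; m4[3, 2] <- 2L
  expect_equal(local_crowding(toy_lattice(m4), 2, 2,
                              interaction_params(2, 0.5)), (3 + 2 * 2) / 8)

  # boundary cell: wall sites contribute nothing, denominator stays 8
  m5 <- matrix(0L, 3, 3); m5[1, 1] <- 1L; m5[1, 2] <- 1L
  expect_equal(local_crowding(toy_lattice(m5), 1, 1, spatial_inter), 1 / 8)

  expect_error(local_crowding(toy_lattice(matrix(0L, 3, 3)), 2, 2,
                              spatial_inter), "empty")
})

test_that("stepping preserves exclusion and honors space gating", {
  phen <- default_spatial_phenotypes()

  # empty lattice stays empty
  e <- step_lattice(toy_lattice(matrix(0L, 10, 10)), phen$r, phen$K,
                    spatial_inter)
  expect_true(all(unclass(e) == 0L))
  expect_equal(attr(e, "time"), 1)

  # fully enclosed immortal cell can neither divide nor move
  pr0 <- phenotype_params("r", 0.9, 1, baseline_death = 0,
                          density_death_coef = 0, motility = 0.9)
  m <- matrix(1L, 3, 3)
  set.seed(4)
  out <- step_lattice(toy_lattice(m), pr0, phen$K,
                      interaction_params(0, 0))
  expect_equal(unclass(out), m, ignore_attr = TRUE)

  # occupancy codes stay in {0, 1, 2} through many crowded steps
  cfg <- spatial_config(width = 15, height = 15, seeding_radius = 4,
                        total_seeded = 40, n_replicates = 1)
  set.seed(8)
  lat <- seed_lattice(cfg)
  for (i in 1:30) lat <- step_lattice(lat, phen$r, phen$K, spatial_inter)
  expect_true(all(unclass(lat) %in% 0:2))
})

test_that("an uncrowded immortal cell line grows like a branching process", {
  # until a cell is fully enclosed, division is unimpeded, so E[N] after
  # t sweeps is exactly (1 + p_div)^t; 20 sweeps keeps clusters small
  # enough that enclosure is negligible
  pr <- phenotype_params("r", 0.1, 1, baseline_death = 0,
                         density_death_coef = 0, motility = 0.2)
  pk <- default_spatial_phenotypes()$K
  n_rep <- 800
  set.seed(21)
  finals <- replicate(n_rep, {
    m <- matrix(0L, 41, 41); m[21, 21] <- 1L
    lat <- toy_lattice(m)
    for (i in 1:20) lat <- step_lattice(lat, pr, pk,
                                        interaction_params(0, 0))
    sum(unclass(lat) == 1L)
  })
  se <- stats::sd(finals) / sqrt(n_rep)
  expect_lt(abs(mean(finals) - 1.1^20), 3 * se)
})

test_that("without density death or motility growth is at most geometric", {
  pr <- phenotype_params("r", 0.3, 1, baseline_death = 0,
                         density_death_coef = 0, motility = 0)
  pk <- default_spatial_phenotypes()$K
  set.seed(12)
  finals <- replicate(30, {
    m <- matrix(0L, 61, 61)
    m[29:32, 29:32] <- 1L
    lat <- toy_lattice(m)
    n <- 16L
    for (i in 1:25) {
      lat <- step_lattice(lat, pr, pk, interaction_params(0, 0))
      n_new <- sum(unclass(lat) == 1L)
      expect_lte(n_new, 2L * n)  # at most one daughter per cell per sweep
      expect_gte(n_new, n)       # no deaths configured
      n <- n_new
    }
    n
  })
  # space gating keeps mean growth below the free branching expectation
  expect_lt(mean(finals), 16 * 1.3^25)
})

test_that("segregation index has the right sign, symmetry and null", {
  # mirror-symmetric placement: exactly 0
  m <- matrix(0L, 11, 11)
  m[6, 2] <- 1L; m[6, 10] <- 2L
  m[2, 6] <- 1L; m[10, 6] <- 2L
  expect_equal(segregation_index(toy_lattice(m)), 0)

  # r on the rim, K at the center: strongly positive
  m2 <- matrix(0L, 11, 11)
  m2[1, ] <- 1L; m2[11, ] <- 1L; m2[, 1] <- 1L; m2[, 11] <- 1L
  m2[5:7, 5:7] <- 2L
  expect_gt(segregation_index(toy_lattice(m2)), 0.5)

  # one type absent: undefined
  m3 <- matrix(0L, 5, 5); m3[2, 2] <- 1L
  expect_true(is.na(segregation_index(toy_lattice(m3))))

  # permutation null centred on 0 for random labelling of a disc
  cfg <- spatial_config(width = 31, height = 31, seeding_radius = 10,
                        total_seeded = 200, n_replicates = 1)
  set.seed(14)
  lat <- seed_lattice(cfg)
  occ <- unclass(lat)
  idx <- which(occ > 0)
  null <- replicate(500, {
    shuf <- occ
    shuf[idx] <- sample(occ[idx])
    segregation_index(toy_lattice(shuf))
  })
  expect_lt(abs(mean(null)), 3 * stats::sd(null) / sqrt(500))
})

test_that("label symmetry makes expected segregation zero", {
  # identical phenotypes and alpha = beta: the labels are exchangeable
  p_same_r <- phenotype_params("r", 0.06, 1, 0.002, 0.05, 0.1)
  p_same_k <- phenotype_params("K", 0.06, 1, 0.002, 0.05, 0.1)
  cfg <- spatial_config(width = 41, height = 41, seeding_radius = 10,
                        total_seeded = 200, horizon = 30,
                        snapshot_times = 30, n_replicates = 60,
                        rng_seed = 15)
  res <- run_spatial(p_same_r, p_same_k, interaction_params(1, 1), cfg)
  segs <- vapply(res$snapshots,
                 function(s) segregation_index(s[["30"]]), numeric(1))
  segs <- segs[!is.na(segs)]
  se <- stats::sd(segs) / sqrt(length(segs))
  expect_lt(abs(mean(segs)), 3 * se)
})

test_that("replicate runs are seed-deterministic and well-recorded", {
  phen <- default_spatial_phenotypes()
  cfg <- spatial_config(width = 25, height = 25, seeding_radius = 6,
                        total_seeded = 60, horizon = 10,
                        snapshot_times = 10, n_replicates = 2,
                        rng_seed = 77)
  a <- run_spatial(phen$r, phen$K, spatial_inter, cfg)
  b <- run_spatial(phen$r, phen$K, spatial_inter, cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$snapshots, b$snapshots)

  # counts consistent with snapshots at matching times
  final <- a$snapshots[[1]][["10"]]
  tallies <- c(sum(unclass(final) == 1L), sum(unclass(final) == 2L))
  row <- a$counts[a$counts$replicate == 1 & a$counts$time_h == 10, ]
  expect_equal(c(row$n_r, row$n_K), tallies)

  # zero horizon returns the seeded state only
  cfg0 <- spatial_config(width = 25, height = 25, seeding_radius = 6,
                         total_seeded = 60, horizon = 0,
                         snapshot_times = numeric(0), n_replicates = 1,
                         rng_seed = 3)
  r0 <- run_spatial(phen$r, phen$K, spatial_inter, cfg0)
  expect_equal(nrow(r0$counts), 1L)
  expect_equal(r0$counts$total, 60)
})

test_that("growth-rate series matches direct recomputation", {
  phen <- default_spatial_phenotypes()
  cfg <- spatial_config(width = 31, height = 31, seeding_radius = 8,
                        total_seeded = 120, horizon = 20,
                        snapshot_times = numeric(0), n_replicates = 5,
                        rng_seed = 19)
  res <- run_spatial(phen$r, phen$K, spatial_inter, cfg)
  gr <- growth_rate_series(res)

  # brute-force recomputation from the stored curves
  for (t in c(0, 7, 19)) {
    rates <- sapply(1:5, function(r) {
      d <- res$counts[res$counts$replicate == r, ]
      (d$total[d$time_h == t + 1] - d$total[d$time_h == t]) /
        d$total[d$time_h == t]
    })
    expect_equal(gr$mean_rate[gr$time_h == t], mean(rates))
    expect_equal(gr$sd_rate[gr$time_h == t], stats::sd(rates))
  }

  # constant population: zero rate everywhere (no events possible)
  p_inert <- phenotype_params("r", 1e-9, 1, 0, 0, 0)
  cfgi <- spatial_config(width = 15, height = 15, seeding_radius = 4,
                         total_seeded = 20, init_fraction_r = 1,
                         horizon = 5, snapshot_times = numeric(0),
                         n_replicates = 2, rng_seed = 4)
  resi <- run_spatial(p_inert, p_inert, interaction_params(0, 0), cfgi)
  gri <- growth_rate_series(resi)
  expect_true(all(abs(gri$mean_rate) < 1e-6))
})

test_that("lattice snapshots round-trip through plain text", {
  cfg <- spatial_config(width = 12, height = 9, seeding_radius = 3,
                        total_seeded = 15, n_replicates = 1)
  set.seed(6)
  lat <- seed_lattice(cfg)
  path <- withr::local_tempfile(fileext = ".txt")
  write_lattice(lat, path)
  back <- read_lattice(path)
  expect_equal(unclass(back), unclass(lat), ignore_attr = TRUE)

  # raster export: r cells green, K cells red, empties black
  img_path <- withr::local_tempfile(fileext = ".png")
  write_lattice_image(lat, img_path)
  img <- png::readPNG(img_path)
  occ <- unclass(lat)
  expect_equal(img[, , 2] == 1, occ == 1L, ignore_attr = TRUE)
  expect_equal(img[, , 1] == 1, occ == 2L, ignore_attr = TRUE)
})
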