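make_obs <- function(passages, fractions, reps = 1) {
  as_observed_dataset(data.frame(
    replicate = rep(seq_len(reps), each = length(passages)),
    passage = rep(passages, reps),
    fraction_r = rep(fractions, reps)
  ))
}

test_that("trajectory loss is mean squared error over records", {
  sim <- data.frame(passage = 0:5, fraction_r = seq(0.9, 0.4, by = -0.1))

  # perfect match
  expect_equal(trajectory_loss(sim, make_obs(0:5, sim$fraction_r)), 0)

  # constant offset delta gives delta^2
  expect_equal(trajectory_loss(sim, make_obs(0:5, sim$fraction_r + 0.05)),
               0.05^2)

  # random records against a brute-force loop
  set.seed(88)
  obs <- make_obs(sample(0:5, 20, replace = TRUE), stats::runif(20))
  brute <- 0
  for (i in seq_len(nrow(obs))) {
    sim_f <- sim$fraction_r[sim$passage == obs$passage[i]]
    brute <- brute + (obs$fraction_r[i] - sim_f)^2
  }
  expect_equal(trajectory_loss(sim, obs), brute / nrow(obs))

  # a passage the simulation does not cover is an error naming it
  expect_error(trajectory_loss(sim, make_obs(c(1, 7), c(0.5, 0.5))), "7")
})

test_that("observed datasets are validated on construction", {
  expect_error(make_obs(0:1, c(0.5, 1.2)), "fraction_r")
  expect_error(make_obs(c(0, 1.5), c(0.5, 0.5)), "passage")
  expect_error(as_observed_dataset(data.frame(x = 1)), "replicate")
})

test_that("noise-free data from a grid point is recovered exactly", {
  phen <- default_flow_phenotypes()
  cfg <- passage_config(n_passages = 12, seed_size = 1e5,
                        capacity_total = 1e6, init_fraction_r = 0.9,
                        n_replicates = 1)
  for (true in list(c(1.5, 0.5), c(0, 0), c(2.5, 0))) {
    truth <- simulate_passages_ode(phen$r, phen$K,
                                   interaction_params(true[1], true[2]),
                                   cfg)
    obs <- make_obs(truth$passage, truth$fraction_r)
    fit <- fit_interactions(obs, alpha_grid = seq(0, 3, 0.5),
                            beta_grid = c(0, 0.5, 1),
                            pr = phen$r, pk = phen$K, config = cfg)
    expect_equal(c(fit$alpha_hat, fit$beta_hat), true)
    expect_equal(fit$loss, 0, tolerance = 1e-20)
  }
})

test_that("ties break toward parsimony (smaller alpha + beta, then alpha)", {
  # hand-built trajectory table with exact duplicates
  cfg <- passage_config(n_passages = 2, n_replicates = 1)
  gt <- structure(
    list(
      grid = data.frame(alpha = c(2, 0, 1, 1), beta = c(0, 1, 0, 1)),
      fractions = rbind(c(0.9, 0.5, 0.2), c(0.9, 0.5, 0.2),
                        c(0.9, 0.5, 0.2), c(0.9, 0.4, 0.1)),
      mode = "ode", config = cfg, n_sim = NA_integer_,
      rng_seed = NA_integer_
    ),
    class = "grid_trajectories"
  )
  obs <- make_obs(0:2, c(0.9, 0.5, 0.2))
  fit <- fit_interactions(obs, pr = NULL, pk = NULL, config = cfg,
                          trajectories = gt)
  # three exact fits: (2,0), (0,1), (1,0); smallest alpha+beta then alpha
  expect_equal(c(fit$alpha_hat, fit$beta_hat), c(0, 1))
})

test_that("failing grid points get infinite loss, not a crash", {
  # a dt too coarse for the configured rates at high alpha
  pr <- phenotype_params("r", 0.5, 100, baseline_death = 0.02)
  pk <- phenotype_params("K", 0.03, 900, baseline_death = 0.02)
  cfg <- passage_config(n_passages = 2, seed_size = 100,
                        capacity_total = 1000, n_replicates = 2,
                        rng_seed = 1)
  obs <- make_obs(0:2, c(0.9, 0.5, 0.2))
  expect_warning(
    fit <- fit_interactions(obs, alpha_grid = c(0, 40), beta_grid = 0,
                            pr = pr, pk = pk, config = cfg,
                            mode = "stochastic", n_sim = 3),
    "alpha=40"
  )
  surf <- fit$surface
  expect_true(is.infinite(surf$loss[surf$alpha == 40]))
  expect_equal(fit$alpha_hat, 0)
})

test_that("the loss surface is reproducible under fixed seeds", {
  phen <- default_passage_phenotypes()
  cfg <- passage_config(n_passages = 4, n_replicates = 5, rng_seed = 3)
  obs <- make_obs(0:4, c(0.9, 0.6, 0.4, 0.2, 0.1))
  f1 <- fit_interactions(obs, alpha_grid = c(0, 2), beta_grid = c(0, 1),
                         pr = phen$r, pk = phen$K, config = cfg,
                         mode = "stochastic", n_sim = 10, rng_seed = 5)
  f2 <- fit_interactions(obs, alpha_grid = c(0, 2), beta_grid = c(0, 1),
                         pr = phen$r, pk = phen$K, config = cfg,
                         mode = "stochastic", n_sim = 10, rng_seed = 5)
  expect_identical(f1$surface, f2$surface)
})

test_that("deterministic and stochastic losses agree at scale", {
  phen <- default_flow_phenotypes(1e5)
  design <- flow_design(rng_seed = 41)
  # dt = 0.1 h keeps the discrete-compounding gap between the stochastic
  # mean and the continuous mean-field model below the noise floor
  cfg <- passage_config(n_passages = 30, seed_size = 1e4,
                        capacity_total = 1e5, dt = 0.1,
                        init_fraction_r = 0.9, n_replicates = 3,
                        rng_seed = 41)
  obs <- gen_flow_fractions(phen$r, phen$K, interaction_params(2.2, 0),
                            design, sim_config = cfg)
  grid_a <- c(1.8, 2.2, 2.6)
  fit_ode <- fit_interactions(obs, alpha_grid = grid_a, beta_grid = 0,
                              pr = phen$r, pk = phen$K, config = cfg,
                              mode = "ode")
  fit_sto <- fit_interactions(obs, alpha_grid = grid_a, beta_grid = 0,
                              pr = phen$r, pk = phen$K, config = cfg,
                              mode = "stochastic", n_sim = 200,
                              rng_seed = 13)
  expect_equal(fit_ode$alpha_hat, fit_sto$alpha_hat)
  expect_lt(abs(fit_ode$loss - fit_sto$loss) /
              max(fit_ode$loss, 1e-12), 0.1)
})

test_that("recovery is unbiased across true interaction strengths", {
  phen <- default_flow_phenotypes()
  cfg <- flow_sim_config(flow_design())
  grid_a <- seq(0, 4, 0.2)
  gt <- grid_trajectories(grid_a, 0, phen$r, phen$K, cfg, mode = "ode")
  for (true_a in c(0, 1, 2.2, 3)) {
    hats <- sapply(1:5, function(i) {
      d <- gen_flow_fractions(phen$r, phen$K,
                              interaction_params(true_a, 0),
                              flow_design(rng_seed = 1000 * true_a + i))
      fit_interactions(d, pr = phen$r, pk = phen$K, config = cfg,
                       trajectories = gt)$alpha_hat
    })
    expect_lt(abs(mean(hats) - true_a), 0.2 + 1e-9)
  }
})

test_that("fit results and surfaces round-trip to text", {
  phen <- default_flow_phenotypes()
  cfg <- passage_config(n_passages = 3, seed_size = 1e5,
                        capacity_total = 1e6, n_replicates = 1)
  truth <- simulate_passages_ode(phen$r, phen$K,
                                 interaction_params(1, 0), cfg)
  obs <- make_obs(truth$passage, truth$fraction_r)
  fit <- fit_interactions(obs, alpha_grid = c(0, 1), beta_grid = 0,
                          pr = phen$r, pk = phen$K, config = cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_loss_surface(fit, path)
  back <- utils::read.csv(path)
  expect_equal(back$loss, fit$surface$loss, tolerance = 1e-12)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_fraction_data(obs, p2)
  expect_equal(read_fraction_data(p2)$fraction_r, obs$fraction_r,
               tolerance = 1e-12)
})
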