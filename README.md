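# rkcompete

Competition dynamics of r- and K-selected tumor cell populations.

Density-dependent selection pushes cell populations toward one of two
life-history strategies: *r*-selected cells divide fast at low density
but die under crowding, while *K*-selected cells divide slowly,
tolerate crowding and carry a higher capacity. `rkcompete` models the
competition between two such derived phenotypes in co-culture, for
researchers studying density-dependent selection, experimental
evolution in cell lines, or intra-tumor ecological interactions.

At its core is the two-type Lotka–Volterra competition model

    dn_r/dt = r_r n_r (1 − (n_r + α n_K)/K_r)
    dn_K/dt = r_K n_K (1 − (n_K + β n_r)/K_K)

where α weights the crowding effect of K cells on r cells and β the
reverse. Around it the package provides:

* `integrate_lv()`, `classify_outcome()` — deterministic dynamics
  (fixed-step RK4) and invasion-criterion outcome classification;
* `simulate_passages()`, `dilute()`, `extinction_passage()` — a
  stochastic binomial birth–death simulator of serial passages with
  hypergeometric dilution, for fraction trajectories and extinction
  times;
* `run_spatial()`, `segregation_index()`, `growth_rate_series()` — an
  on-lattice agent-based model (Rcpp core) with density-dependent
  division, death and migration, reproducing center/periphery niche
  separation and the growth advantage of mixed populations;
* `fit_interactions()`, `grid_trajectories()` — grid-search estimation
  of (α, β) from fraction-versus-passage data by mean-squared-error
  minimisation, with deterministic and stochastic modes;
* `gen_flow_fractions()`, `gen_reference_fig4d()` — synthetic
  flow-cytometry-style datasets with binomial gating noise, including
  the shipped synthetic reference dataset
  (`inst/extdata/fig4d_synthetic.csv`);
* `run_experiment()` — canned experiment drivers
  (`fig4d_fractions`, `extinction_vs_alpha`, `spatial_niche`,
  `mixed_fitness`) writing tidy CSV tables plus a JSON manifest, and a
  thin CLI wrapper in `inst/scripts/rkcompete-cli.R`.

See the vignette (`vignettes/rk-competition-methods.Rmd`) for the model
assumptions, default parameter calibration and numerical choices.

## Worked example

Estimate the competition coefficients from the shipped synthetic
reference dataset (9:1 r:K seeding, 3 replicates, 30 passages,
generated at α = 2.2, β = 0 with 10⁴ gated cells per measurement):

```r
library(rkcompete)

phen <- default_flow_phenotypes()          # well-scale life histories
cfg  <- flow_sim_config(flow_design())     # 30 passages, seed 1e5 cells
obs  <- read_fraction_data(reference_fig4d_path())

fit <- fit_interactions(obs, alpha_grid = seq(0, 4, 0.1),
                        beta_grid = c(0, 0.5, 1),
                        pr = phen$r, pk = phen$K, config = cfg)
fit
#> <rk_fit> alpha_hat=2.1 beta_hat=0 loss=5.257e-06 (ode mode, 123 grid points)
```

`alpha_hat = 2.1` (one grid step from the generating value 2.2;
deterministic-mode fitting of stochastic data carries a small
discretisation bias) says one K cell crowds an r cell about as strongly
as two r cells would; `beta_hat = 0` says r cells exert no detectable
reciprocal effect — the asymmetry that makes the r population collapse
in high-density co-culture. The loss is the mean squared deviation
between the fitted mean trajectory and the 93 observed fractions.

A quick look at the corresponding extinction behavior at desk scale:

```r
phen <- default_passage_phenotypes()
cfg  <- passage_config(n_replicates = 100, rng_seed = 1)
res  <- simulate_passages(phen$r, phen$K, interaction_params(2.2, 0), cfg)
median_extinction(extinction_passage(res), horizon = 30)
#> [1] 2
```

Under the fitted interaction the median r-extinction passage is 2; with
`interaction_params(0, 0)` the same call gives 23 — extinction still
happens at this small population scale, but an order of magnitude
later, driven by drift alone.

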