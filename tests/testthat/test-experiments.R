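test_that("experiment specs validate their sweep grids", {
  fld <- std_field(100)
  cfg <- tiny_config()
  expect_error(
    experiment_spec("x", delta_kernel(0, 0), fld, cfg,
                    sweep = list(var = "lag", grid = numeric(0))),
    "non-empty")
  expect_error(
    experiment_spec("x", delta_kernel(0, 0), fld, cfg,
                    sweep = list(var = "lag", grid = c(2, 1))),
    "increasing")
  expect_error(
    experiment_spec("x", "not a kernel", fld, cfg,
                    sweep = list(var = "lag", grid = 1)),
    "kernel")
})

test_that("a small lag sweep runs end to end, deterministically, with provenance", {
  out_dir <- file.path(tempdir(), "rt_sweep_test")
  cfg <- sim_config(v = 10, tau = 1, dt = 0.05, L = 100, n_walkers = 4,
                    t_burn = 150, t_sample = 400, seed = 7)
  spec <- sweep_lag(weight = -0.002, grid = c(0.5, 2), field = std_field(100),
                    config = cfg, seed = 7, out_dir = out_dir)
  res1 <- run_experiment(spec, exclusion = 20, transport_exclusion = 20, n_bins = 20,
                         n_bins_run = 10, quiet = TRUE)
  res2 <- run_experiment(spec, exclusion = 20, transport_exclusion = 20, n_bins = 20,
                         n_bins_run = 10, quiet = TRUE)
  expect_identical(res1, res2)
  expect_equal(nrow(res1), 2)
  expect_true(all(c("slope_sim", "slope_theory", "rel_dev_slope",
                    "vd_sim", "vd_theory", "dDdx_sim") %in% names(res1)))
  expect_true(file.exists(file.path(out_dir, "lag_sweep_results.csv")))
  prov <- readLines(file.path(out_dir, "lag_sweep_provenance.txt"))
  expect_true(any(grepl("kernel.weight", prov)))
  expect_true(any(grepl("config.seed", prov)))
  back <- read.csv(file.path(out_dir, "lag_sweep_results.csv"))
  expect_equal(back$slope_sim, res1$slope_sim, tolerance = 1e-12)
})

test_that("tau sweeps rescale the time step with the run duration", {
  base <- sim_config(v = 10, tau = 1, dt = 0.05, L = 100, n_walkers = 2,
                     t_sample = 100, seed = 3)
  spec <- sweep_tau(bilobe_kernel(), grid = c(0.5, 1), field = std_field(100),
                    base_config = base, seed = 3)
  cfg_half <- spec$config(0.5)
  expect_equal(cfg_half$dt, 0.025)
  expect_equal(cfg_half$tau, 0.5)
})

test_that("fixture generation is deterministic and the planted truths recover", {
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  truth <- generate_fixtures(123, d1)
  generate_fixtures(123, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # planted linear density is recovered by the slope estimator
  pos <- read.csv(file.path(d1, "synthetic_positions.csv"), comment.char = "#")
  est <- estimate_density_slope(split(pos$x, pos$walker), n_bins = 20,
                                L = truth$L, n_boot = 300, seed = 1)
  expect_lt(abs(est$slope_over_level - truth$planted_slope_over_level),
            3 * est$slope_over_level_se)
  # planted drift is recovered by the drift estimator
  runs <- read.csv(file.path(d1, "synthetic_runs.csv"), comment.char = "#")
  dr <- estimate_drift_velocity(runs, L = truth$L, n_boot = 300, seed = 1)
  expect_lt(abs(dr$v_d - truth$planted_vd), 3 * dr$se)
  # bilobe fixture written by the generator is adaptive after rebalance
  kb <- read_kernel(file.path(d1, "bilobe_fixture.csv"), rebalance = TRUE)
  expect_equal(sum(kb$weight), 0, tolerance = 1e-15)
  expect_true(file.exists(file.path(d1, "golden_theory.json")))
})

test_that("transport-fit results round-trip through the on-disk format", {
  cfg <- sim_config(v = 10, tau = 1, dt = 0.05, L = 100, n_walkers = 4,
                    t_burn = 150, t_sample = 500, seed = 19)
  ens <- simulate_ensemble(delta_kernel(0.5, -0.002), std_field(100), cfg,
                           n_bins = 20, n_bins_run = 10)
  fit <- fit_transport(ens, exclusion = 20, n_boot = 200)
  d <- file.path(tempdir(), "rt_fit_out")
  write_transport_fit(fit, d)
  dens <- read.csv(file.path(d, "density.csv"))
  expect_equal(dens$P, fit$density$bins$P)
  summ <- if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::read_json(file.path(d, "summary.json"))
  else NULL
  if (!is.null(summ)) {
    expect_equal(summ$v_d, fit$drift$v_d, tolerance = 1e-12)
    expect_equal(summ$D0, fit$diffusivity$D0, tolerance = 1e-12)
  }
})
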