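test_that("tumble probability implements the clamped linear law", {
  expect_equal(tumble_probability(0, 0.05, 1), 0.05)
  expect_equal(tumble_probability(1, 0.05, 1), 0)
  expect_equal(tumble_probability(-1, 0.05, 1), 0.1)
  expect_equal(tumble_probability(-1e6, 0.05, 1), 1)      # clamped above
  expect_equal(tumble_probability(1e6, 0.05, 1), 0)       # clamped below
  # threshold mode zeroes only a negative functional
  expect_equal(tumble_probability(-0.5, 0.05, 1, "threshold_linear"), 0.05)
  expect_equal(tumble_probability(0.5, 0.05, 1, "threshold_linear"),
               tumble_probability(0.5, 0.05, 1, "linear"))
  expect_equal(tumble_probability(c(0, 1, -1), 0.05, 1),
               c(0.05, 0, 0.1))
})

test_that("reflection mirrors positions, flips direction, flags overshoot", {
  L <- 100
  r <- apply_reflection(L + 0.5, 1, L, step = 0.5)
  expect_equal(r$x, L - 0.5); expect_equal(r$direction, -1)
  r <- apply_reflection(-0.5, -1, L, step = 0.5)
  expect_equal(r$x, 0.5); expect_equal(r$direction, 1)
  r <- apply_reflection(42, 1, L, step = 0.5)
  expect_equal(r$x, 42); expect_equal(r$direction, 1)
  expect_error(apply_reflection(L + 1, 1, L, step = 0.5), "overshoot")
})

test_that("configuration validation enforces the discretisation contracts", {
  expect_error(sim_config(dt = 0.2, tau = 1), "dt <= tau / 10")
  expect_error(sim_config(p_r = 0), "p_r")
  expect_error(sim_config(p_r = 1.2), "p_r")
  expect_error(sim_config(L = 1000.03, dt = 0.01), "lattice")
  expect_warning(
    simulate_ensemble(delta_kernel(0, 0), std_field(100),
                      tiny_config(t_burn = 5, t_sample = 10)),
    "burn-in")
  expect_error(conc_field(-1, 0), "non-negative")
  expect_error(
    simulate_ensemble(delta_kernel(0, 0), conc_field(1, -0.5),
                      tiny_config()),
    "non-negative")
  expect_warning(
    check_weak_gradient(delta_kernel(0, 0.02), std_field(100),
                        tiny_config()),
    "linear response")
})

test_that("simulation is deterministic given the seed", {
  k <- delta_kernel(0.5, -0.002)
  e1 <- suppressWarnings(
    simulate_ensemble(k, std_field(100), tiny_config(seed = 99),
                      record_runs = TRUE, record_steps = TRUE))
  e2 <- suppressWarnings(
    simulate_ensemble(k, std_field(100), tiny_config(seed = 99),
                      record_runs = TRUE, record_steps = TRUE))
  expect_identical(e1$hist, e2$hist)
  expect_identical(e1$steps, e2$steps)
  expect_identical(e1$runs, e2$runs)
  e3 <- suppressWarnings(
    simulate_ensemble(k, std_field(100), tiny_config(seed = 100)))
  expect_false(identical(e1$hist, e3$hist))
})

test_that("trajectories respect the lattice, the box and the run book-keeping", {
  cfg <- tiny_config(t_burn = 0, t_sample = 200, seed = 3)
  ens <- suppressWarnings(
    simulate_ensemble(delta_kernel(0.5, -0.002), std_field(100), cfg,
                      record_runs = TRUE, record_steps = TRUE))
  st <- ens$steps
  expect_true(all(st$x >= 0 & st$x <= cfg$L))
  step_len <- cfg$v * cfg$dt
  expect_true(all(abs(st$x / (step_len / 2) -
                        round(st$x / (step_len / 2))) < 1e-9))
  for (w in unique(st$walker)) {
    dx <- abs(diff(st$x[st$walker == w]))
    expect_true(all(abs(dx - step_len) < 1e-9 | dx < 1e-9))
  }
  runs <- ens$runs
  expect_true(all(runs$duration_s >= cfg$dt - 1e-12))
  kdur <- runs$duration_s / cfg$dt
  expect_true(all(abs(kdur - round(kdur)) < 1e-9))
  expect_true(all(abs(runs$displacement_um) <= cfg$v * runs$duration_s + 1e-9))
})

test_that("the compiled functional agrees with the reference implementation", {
  # dual route: replay the recorded positions through evaluate_functional()
  kern <- response_kernel(c(0.25, 0.6, 1.5), c(0.003, -0.001, -0.002))
  cfg <- tiny_config(t_burn = 0, t_sample = 60, n_walkers = 2, seed = 21)
  fld <- std_field(100)
  ens <- suppressWarnings(
    simulate_ensemble(kern, fld, cfg, record_steps = TRUE,
                      check_gradient = FALSE))
  st <- ens$steps
  for (w in 1:2) {
    sw <- st[st$walker == w, ]
    conc <- field_at(fld, sw$x)
    fill <- field_at(fld, ens$x0[w])
    h <- concentration_history(conc, dt = cfg$dt, fill = fill)
    idx <- c(5, 17, 100, 600, nrow(sw))
    for (i in idx) {
      expect_equal(sw$F[i], evaluate_functional(kern, h, now = i),
                   tolerance = 1e-12)
    }
  }
})

test_that("an adaptive kernel in a uniform field reproduces the null walk exactly", {
  # F is identically zero, so the same seed must give the same trajectory
  cfg <- tiny_config(t_burn = 0, t_sample = 100, seed = 8)
  fld <- conc_field(20, 0)
  e0 <- suppressWarnings(
    simulate_ensemble(delta_kernel(0, 0), fld, cfg, record_steps = TRUE))
  ea <- suppressWarnings(
    simulate_ensemble(two_delta_kernel(0.3, 1.2, 0.005), fld, cfg,
                      record_steps = TRUE))
  expect_identical(e0$steps$x, ea$steps$x)
  expect_identical(e0$steps$tumbled, ea$steps$tumbled)
})

test_that("null run durations are geometric with mean tau", {
  cfg <- tiny_config(n_walkers = 4, t_burn = 10, t_sample = 600, seed = 13)
  ens <- suppressWarnings(
    simulate_ensemble(delta_kernel(0, 0), std_field(100), cfg,
                      record_runs = TRUE))
  k <- round(ens$runs$duration_s / cfg$dt)
  expect_gt(length(k), 1500)
  m <- mean(ens$runs$duration_s)
  expect_lt(abs(m - cfg$tau), 3 * sd(ens$runs$duration_s) / sqrt(length(k)))
  # randomised PIT against the geometric law is uniform under H0
  p0 <- cfg$dt / cfg$tau
  set.seed(1)
  u <- pgeom(k - 2, p0) + runif(length(k)) * dgeom(k - 1, p0)
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("finite tumble duration suspends translation but not memory", {
  cfg <- tiny_config(t_burn = 0, t_sample = 120, tau_t = 0.2, seed = 17)
  ens <- suppressWarnings(
    simulate_ensemble(delta_kernel(0.5, -0.002), std_field(100), cfg,
                      record_steps = TRUE, record_runs = TRUE))
  st <- ens$steps[ens$steps$walker == 1, ]
  tum <- which(st$tumbled == 1)
  tum <- tum[tum + 4 <= nrow(st)]
  for (i in tum) {
    # four steps (tau_t / dt) without translation after each tumble
    expect_true(all(abs(diff(st$x[i:(i + 4)])) < 1e-12))
  }
  # runs are still timed in whole steps and positive
  expect_true(all(ens$runs$duration_s >= cfg$dt - 1e-12))
})

test_that("an empty ensemble yields an empty trajectory list", {
  cfg <- tiny_config(n_walkers = 0, t_burn = 0, t_sample = 10)
  expect_identical(
    suppressWarnings(run_ensemble(delta_kernel(0, 0), std_field(100), cfg)),
    list())
})

test_that("the null walk fills the box uniformly", {
  cfg <- sim_config(v = 10, tau = 1, dt = 0.05, L = 100, n_walkers = 16,
                    t_sample = 4000, seed = 29)
  ens <- simulate_ensemble(delta_kernel(5, 0), std_field(100), cfg,
                           n_bins = 20)
  est <- estimate_density_slope(ens, exclusion = 10)
  expect_lt(abs(est$slope_over_level), 3 * est$slope_over_level_se)
  # chi-squared against uniform with walker-level bin errors
  keep <- est$bins
  z <- (keep$P - mean(keep$P)) / keep$P_err
  chisq <- sum(z^2)
  expect_gt(pchisq(chisq, nrow(keep) - 1, lower.tail = FALSE), 1e-3)
})

test_that("threshold-linear mode zeroes unfavourable functionals in the core", {
  kern <- delta_kernel(0.5, -0.002)   # negative weight: F < 0 where c > 0
  cfg <- tiny_config(t_burn = 0, t_sample = 60, n_walkers = 2, seed = 23,
                     response = "threshold_linear")
  fld <- std_field(100)
  ens <- suppressWarnings(
    simulate_ensemble(kern, fld, cfg, record_steps = TRUE))
  st <- ens$steps
  expect_true(all(st$F >= 0))
  # recorded F equals the thresholded replay of the reference functional
  sw <- st[st$walker == 1, ]
  h <- concentration_history(field_at(fld, sw$x), dt = cfg$dt,
                             fill = field_at(fld, ens$x0[1]))
  for (i in c(30, 200, 800)) {
    expect_equal(sw$F[i], max(evaluate_functional(kern, h, now = i), 0),
                 tolerance = 1e-12)
  }
})
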