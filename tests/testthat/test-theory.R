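cfg0 <- sim_config(v = 10, tau = 1, dt = 0.05, L = 200, n_walkers = 0,
                   t_sample = 0, seed = 1)
fld0 <- conc_field(5, 0.2)

test_that("memoryless drift cancels the diffusivity gradient identically", {
  for (a in c(-0.003, 0.001)) {
    for (p_r in c(0.25, 0.5, 1)) {
      for (tau in c(0.5, 1, 2)) {
        cfg <- sim_config(v = 10, tau = tau, dt = tau / 20, L = 200,
                          p_r = p_r, n_walkers = 0, t_sample = 0)
        th <- transport_theory(delta_kernel(0, a), cfg, fld0)
        expect_equal(th$v_d, th$dDdx, tolerance = 1e-14)
        expect_equal(th$slope, 0, tolerance = 1e-18)
      }
    }
  }
})

test_that("drift velocity: zero cases, adaptive sign, exponential lag decay", {
  expect_identical(degennes_drift(delta_kernel(1, 0), cfg0, fld0), 0)
  expect_identical(
    degennes_drift(delta_kernel(1, 0.002), cfg0, conc_field(5, 0)), 0)
  # adaptive two-delta kernel with T1 < T2 and a > 0 drifts up-gradient
  expect_gt(degennes_drift(two_delta_kernel(0.3, 3, 0.002), cfg0, fld0), 0)
  # decay ratio is exp(-T / tau_dir) with tau_dir = tau / (2 p_r)
  v0 <- degennes_drift(delta_kernel(0, 0.002), cfg0, fld0)
  v1 <- degennes_drift(delta_kernel(1, 0.002), cfg0, fld0)
  v2 <- degennes_drift(delta_kernel(2, 0.002), cfg0, fld0)
  tdir <- direction_decorrelation_time(cfg0)
  expect_equal(v1 / v0, exp(-1 / tdir), tolerance = 1e-12)
  expect_equal(v2 / v0, exp(-2 / tdir), tolerance = 1e-12)
})

test_that("diffusivity field is linear in concentration with adaptive cancellation", {
  k <- delta_kernel(1, -0.002)
  df <- diffusivity_field(k, cfg0, fld0)
  Dfree <- free_diffusivity(cfg0)
  expect_equal(df$D_free, Dfree)
  expect_equal(df$D0, Dfree * (1 - 0.002 * 5))
  expect_equal(df$dDdx, Dfree * 0.2 * (-0.002))
  expect_equal(df$D_fun(100), df$D0 + 100 * df$dDdx)
  # zero kernel: free diffusivity everywhere
  dz <- diffusivity_field(delta_kernel(0, 0), cfg0, fld0)
  expect_equal(dz$D0, Dfree); expect_equal(dz$dDdx, 0)
  # adaptive kernels: exactly uniform diffusivity
  da <- diffusivity_field(two_delta_kernel(0.5, 2, 0.002), cfg0, fld0)
  expect_equal(da$dDdx, 0, tolerance = 1e-18)
  db <- diffusivity_field(bilobe_kernel(), cfg0, fld0)
  expect_equal(db$dDdx, 0, tolerance = 1e-16)
})

test_that("zero-flux slope formula: signs, errors, adaptive shortcut", {
  expect_error(steady_state_slope(list(v_d = 1, dDdx = 0, D0 = -1, L = 10)),
               "positive")
  # accumulation by a diffusivity gradient alone
  expect_gt(steady_state_slope(list(v_d = 0, dDdx = -0.05, D0 = 100, L = 10)),
            0)
  # adaptive case reduces to P0 * v_d / D0
  th <- transport_theory(two_delta_kernel(0.3, 2.5, 0.002), cfg0, fld0)
  expect_equal(th$slope, th$v_d / (th$D0 * cfg0$L), tolerance = 1e-14)
  expect_gt(th$slope, 0)
})

test_that("slopes superpose linearly over kernel impulses", {
  slope_fn <- function(lag, weight) {
    transport_theory(delta_kernel(lag, weight), cfg0, fld0)$slope
  }
  k1 <- delta_kernel(0.7, 0.0015)
  expect_equal(superpose_slopes(k1, slope_fn), slope_fn(0.7, 0.0015))
  # superposition is a linear-order identity: the per-impulse slopes carry
  # an O(a * c0) denominator correction, so agreement is to a few percent
  k2 <- two_delta_kernel(0.5, 2, 0.002)
  expect_equal(superpose_slopes(k2, slope_fn),
               transport_theory(k2, cfg0, fld0)$slope, tolerance = 0.05)
  # equal and opposite impulses at the same lag cancel (to linear order)
  kz <- response_kernel(c(1, 1), c(0.002, -0.002))
  scale <- abs(slope_fn(1, 0.002))
  expect_lt(abs(superpose_slopes(kz, slope_fn)), 0.05 * scale)
  # bilobe slope from superposition matches the direct theory
  kb <- bilobe_kernel()
  expect_equal(superpose_slopes(kb, slope_fn),
               transport_theory(kb, cfg0, fld0)$slope, tolerance = 0.05)
})

test_that("two-delta slope magnitude grows with the lag separation", {
  th <- vapply(c(1, 2, 4, 8), function(T2) {
    transport_theory(two_delta_kernel(0.5, T2, 0.002), cfg0, fld0)$slope
  }, numeric(1))
  expect_true(all(diff(abs(th)) > 0))
})

test_that("two-species mapping represents adaptive but not non-adaptive transport", {
  # V = 0, uniform D: symmetric rates and purely diffusive flux
  m0 <- schnitzer_map(list(v_d = 0, D0 = 100, dDdx = 0, L = 200), cfg0)
  expect_equal(m0$alpha_plus, m0$alpha_minus)
  expect_equal(m0$flux_coef_P, 0)
  expect_true(m0$representable)
  # adaptive case: flux recovered equals V P - D dP/dx
  tha <- transport_theory(two_delta_kernel(0.3, 2, 0.002), cfg0, fld0)
  ma <- schnitzer_map(tha, cfg0)
  expect_true(ma$representable)
  P <- 1 / cfg0$L; dP <- tha$slope
  flux_two_species <- ma$flux_coef_P * P + ma$flux_coef_dP * dP
  flux_model <- tha$v_d * P - tha$D_centre * dP   # dDdx = 0
  expect_equal(flux_two_species, flux_model, tolerance = 1e-12)
  # rate asymmetry carries the drift
  expect_equal(cfg0$v * (ma$alpha_minus - ma$alpha_plus) / ma$rate_sum,
               tha$v_d, tolerance = 1e-12)
  # non-adaptive case with V = 0 but dD/dx != 0 is flagged
  mn <- schnitzer_map(list(v_d = 0, D0 = 100, dDdx = -0.05, L = 200), cfg0)
  expect_false(mn$representable)
  expect_true(mn$drift_two_species != 0)
})
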