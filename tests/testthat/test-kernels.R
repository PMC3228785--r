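test_that("kernel constructors validate their inputs and classify adaptivity", {
  expect_error(delta_kernel(-1, 0.1), "finite and >= 0")
  expect_error(delta_kernel(0, Inf), "finite")
  expect_error(response_kernel(numeric(0), numeric(0)), "at least one")
  expect_error(two_delta_kernel(2, 2, 0.1), "strictly smaller")
  expect_error(two_delta_kernel(3, 2, 0.1), "strictly smaller")
  expect_error(two_delta_kernel(1, 2, -0.1), "positive")
  expect_error(bilobe_kernel(data.frame(lag_s = numeric(0), weight = numeric(0))),
               "empty")
  expect_error(bilobe_kernel(data.frame(lag_s = c(1, 1, 2), weight = c(1, 2, 3))),
               "strictly increasing")

  expect_false(delta_kernel(0.5, 0.01)$adaptive)
  expect_true(delta_kernel(0.5, 0)$adaptive)      # null kernel
  k2 <- two_delta_kernel(0.5, 2, 0.003)
  expect_true(k2$adaptive)
  expect_identical(sum(k2$weight), 0)             # exact by construction
  expect_equal(k2$max_lag, 2)
})

test_that("packaged bilobe fixture has the documented shape", {
  tab <- bilobe_table()
  expect_true(all(diff(tab$lag_s) > 0))
  # positive early lobe, shallower negative late lobe
  expect_gt(max(tab$weight), 0)
  expect_lt(min(tab$weight), 0)
  expect_lt(tab$lag_s[which.max(tab$weight)], tab$lag_s[which.min(tab$weight)])
  expect_gt(max(tab$weight), abs(min(tab$weight)))
  # raw area close to zero: adaptive at the default 1e-2 relative tolerance
  raw <- bilobe_kernel(rebalance = FALSE)
  expect_true(is_adaptive(raw, tol = 1e-2))
  expect_false(is_adaptive(raw, tol = 1e-4))      # flag reflects the raw sum
  reb <- bilobe_kernel()
  expect_equal(sum(reb$weight), 0, tolerance = 1e-15)
  # all-zero table gives the null kernel
  z <- bilobe_kernel(data.frame(lag_s = 1:3, weight = c(0, 0, 0)),
                     rebalance = FALSE)
  expect_true(z$adaptive)
  expect_identical(sum(abs(z$weight)), 0)
})

test_that("kernel CSV round-trips, with comments allowed", {
  k <- two_delta_kernel(0.25, 1.75, 0.004)
  path <- tempfile(fileext = ".csv")
  write_kernel(k, path, comment = "round-trip test")
  k2 <- read_kernel(path)
  expect_equal(k2$lag, k$lag)
  expect_equal(k2$weight, k$weight)
  expect_true(k2$adaptive)
})

test_that("memory functional matches its defining examples", {
  dt <- 0.1
  # single delta with lagged concentration C gives a * C
  h <- concentration_history(c(7, 3, 9, 4), dt = dt)
  expect_equal(evaluate_functional(delta_kernel(0.2, 2), h), 2 * 3)
  expect_equal(evaluate_functional(delta_kernel(0, 2), h), 2 * 4)
  # adaptive kernel on a uniform history is exactly zero
  hu <- concentration_history(rep(5, 50), dt = dt)
  expect_identical(evaluate_functional(two_delta_kernel(0.5, 2, 0.01), hu), 0)
  # moving up-gradient between t - T2 and t - T1 gives F > 0
  hup <- concentration_history(seq(1, 5, length.out = 41), dt = dt)
  expect_gt(evaluate_functional(two_delta_kernel(0.5, 2, 0.01), hup), 0)
  # pre-history queries fall back to the fill value
  hs <- concentration_history(c(2, 8), dt = dt, fill = 2)
  expect_equal(evaluate_functional(delta_kernel(1, 1), hs), 2)
})

test_that("lags round to the nearest step with ties rounding up", {
  dt <- 0.1
  h <- concentration_history(c(1, 2, 3), dt = dt)
  # lag 0.15 s: between steps 1 and 2, tie at 1.5 -> 2 steps -> values[1]
  expect_equal(evaluate_functional(delta_kernel(0.15, 1), h), 1)
  # lag 0.14 rounds down to 1 step -> values[2]
  expect_equal(evaluate_functional(delta_kernel(0.14, 1), h), 2)
})

test_that("functional is linear, translation-covariant and gradient-scaling", {
  set.seed(42)
  dt <- 0.05
  for (i in 1:5) {
    vals <- runif(80, 1, 10)
    h <- concentration_history(vals, dt = dt)
    k1 <- response_kernel(sort(runif(3, 0, 3)), rnorm(3, 0, 0.01))
    k2 <- response_kernel(sort(runif(4, 0, 3)), rnorm(4, 0, 0.01))
    w1 <- rnorm(1); w2 <- rnorm(1)
    ks <- combine_kernels(k1, k2, w1, w2)
    expect_equal(evaluate_functional(ks, h),
                 w1 * evaluate_functional(k1, h) +
                   w2 * evaluate_functional(k2, h),
                 tolerance = 1e-12)
    # adding a constant shifts F by sum(a) * const; no shift when adaptive
    const <- 2.5
    h2 <- concentration_history(vals + const, dt = dt, fill = vals[1] + const)
    expect_equal(evaluate_functional(k1, h2),
                 evaluate_functional(k1, h) + sum(k1$weight) * const,
                 tolerance = 1e-12)
    ka <- two_delta_kernel(0.3, 1.7, 0.01)
    expect_equal(evaluate_functional(ka, h2), evaluate_functional(ka, h),
                 tolerance = 1e-12)
    # scaling the gradient part scales F for adaptive kernels
    lambda <- 3
    c0 <- 5
    h3 <- concentration_history(c0 + lambda * (vals - c0) + 20, dt = dt)
    hb <- concentration_history(vals, dt = dt)
    expect_equal(evaluate_functional(ka, h3),
                 lambda * evaluate_functional(ka, hb),
                 tolerance = 1e-10)
  }
})
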