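# Reduced-scale reference studies.
#
# These functions reproduce, at desk scale, the package's central
# quantitative claims: null behaviour of the unbiased walk, memoryless
# cancellation, sign antisymmetry, scaling collapse and saturation of the
# slope, small-lag linearity, the exponential lag decay and spatial
# uniformity of the drift velocity, the linear diffusivity profile and its
# adaptive cancellation, the zero-flux closure, superposition of impulse
# slopes, the bilobe optimum, tumble-duration insensitivity, and gradient
# linearity.
#
# Study conditions are frozen: walker physics at the package defaults
# (v = 10 um/s, tau = 1 s, p_r = 1/2, modulation capped at |F| <= 0.1 via
# |a| * max c = 0.1), boxes of 10-30 run lengths, and sampling times sized
# by an a-priori power analysis (see the methods vignette) so that each
# check resolves its target at the tolerance being asserted. The time step
# is tau/10 except where a component needs finer resolution: the small-lag
# grid and the bilobe lag table require dt to divide the lags, and the
# diffusivity-gradient comparison against linear theory keeps dt = tau/20
# because its discretisation bias adds to an O(10%) finite-modulation
# deviation inside a 15% band. Sampling times are never adjusted per seed.

.STUDY <- list(
  v = 10, tau = 1, p_r = 0.5, c0 = 5, a = 0.002, n_walkers = 32L,
  # main geometry: slope sweeps, superposition, tumble pair, gradient pair
  M = list(L = 200, excl = 40, c1 = 0.225),
  # small box: small-lag linearity
  B = list(L = 100, excl = 20, c1 = 0.45),
  # deep-bulk geometry: drift, diffusivity and closure
  # (transport exclusion 90 um = 9 run lengths)
  D = list(L = 240, excl = 40, excl_t = 90, c1 = 0.1875)
)

# one simulated condition at study scale; T_tot is the total sampled
# walker-time in seconds, split over 32 walkers
.study_run <- function(kernel, c1, L, T_tot, seed, tau = 1, dt = tau / 10,
                       c0 = .STUDY$c0, tau_t = 0, record_runs = FALSE) {
  nw <- .STUDY$n_walkers
  config <- sim_config(v = .STUDY$v, tau = tau, dt = dt, p_r = .STUDY$p_r,
                       L = L, tau_t = tau_t, n_walkers = nw,
                       t_sample = T_tot / nw, seed = seed)
  nb <- round(L / (.STUDY$v * tau / 2))
  nbr <- round(L / (.STUDY$v * tau))
  simulate_ensemble(kernel, conc_field(c0, c1), config, n_bins = nb,
                    n_bins_run = nbr, record_runs = record_runs,
                    check_gradient = FALSE)
}

.seed_at <- function(seed, k) (seed + 1009 * k) %% 2147483647

# slope-to-level ratio and bootstrap error of one condition
.slope_of <- function(ens, excl, seed) {
  est <- estimate_density_slope(ens, exclusion = excl, seed = seed)
  c(r = est$slope_over_level, se = est$slope_over_level_se)
}

#' Null model: unbiased run-and-tumble walk
#'
#' Zero-weight kernel in the standard gradient: the stationary density must
#' be flat, run durations geometric with mean `tau`, and the measured
#' diffusivity equal to the telegraph closed form `v^2 tau / (2 p_r)`.
#'
#' @param seed integer seed.
#' @return A list with the slope estimate and z-score, the mean run
#'   duration, the Kolmogorov-Smirnov p-value of the run-duration
#'   distribution against the geometric law (via randomised probability
#'   integral transform), and the relative deviation of the measured
#'   diffusivity from the closed form.
#' @export
study_null <- function(seed = 1) {
  g <- .STUDY$M
  ens <- .study_run(delta_kernel(0, 0), g$c1, g$L, T_tot = 5e7,
                    seed = .seed_at(seed, 1))
  sl <- .slope_of(ens, g$excl, .seed_at(seed, 2))
  dp <- estimate_diffusivity_profile(ens, exclusion = g$excl)
  D_free <- free_diffusivity(ens$config)
  D_mean <- stats::weighted.mean(dp$bins$D, dp$bins$n)
  mean_run <- sum(ens$walker_stats$w_sdur) / sum(ens$walker_stats$w_nruns)
  mean_run_se <- stats::sd(ens$walker_stats$w_sdur /
                             ens$walker_stats$w_nruns) /
    sqrt(.STUDY$n_walkers)

  # KS check on a small recorded-run condition
  ks_ens <- .study_run(delta_kernel(0, 0), g$c1, g$L, T_tot = 4000,
                       seed = .seed_at(seed, 3), record_runs = TRUE)
  k <- round(ks_ens$runs$duration_s / ks_ens$config$dt)
  set.seed(.seed_at(seed, 4))
  k <- k[sample.int(length(k), min(2000L, length(k)))]
  p0 <- ks_ens$config$dt / ks_ens$config$tau
  # randomised PIT: uniform on [F(k-1), F(k)] is exactly U(0,1) under H0
  u <- stats::pgeom(k - 2, p0) +
    stats::runif(length(k)) * stats::dgeom(k - 1, p0)
  ks <- stats::ks.test(u, "punif")

  list(slope = sl[["r"]], slope_se = sl[["se"]],
       slope_z = sl[["r"]] / sl[["se"]],
       mean_run_s = mean_run, mean_run_se = mean_run_se,
       D_mean = D_mean, D_free = D_free,
       D_rel_dev = D_mean / D_free - 1,
       ks_p = ks$p.value, n_runs_ks = length(k))
}

#' Memoryless cancellation at zero lag
#'
#' A single impulse at `T = 0`: the analytic drift exactly cancels the
#' diffusivity gradient, so the predicted slope vanishes identically and
#' the simulated slope must be consistent with zero.
#'
#' @inheritParams study_null
#' @return A list with the measured slope (z-scored) and the analytic
#'   slope (identically zero).
#' @export
study_memoryless <- function(seed = 1) {
  g <- .STUDY$M
  kern <- delta_kernel(0, -.STUDY$a)
  ens <- .study_run(kern, g$c1, g$L, T_tot = 9.2e7, seed = .seed_at(seed, 11))
  sl <- .slope_of(ens, g$excl, .seed_at(seed, 12))
  th <- transport_theory(kern, ens$config, ens$field)
  list(slope = sl[["r"]], slope_se = sl[["se"]],
       slope_z = sl[["r"]] / sl[["se"]],
       theory_slope = th$slope, theory_vd = th$v_d, theory_dDdx = th$dDdx)
}

#' Lag sweep of the single-delta kernel (main geometry)
#'
#' Slope-to-level ratios for the favourable single-impulse kernel
#' (`a = -0.002`) across lags 0.2-20 s, with the dimensionless
#' normalisation `S_norm = r / (|a| c1)` whose linear theory is
#' `1 - exp(-T / tau_dir)`.
#'
#' @inheritParams study_null
#' @return A data frame `lag, r, se, S_norm, S_norm_se, S_norm_theory`.
#' @export
study_lag_sweep <- function(seed = 1) {
  g <- .STUDY$M
  lags <- c(0.2, 0.5, 1, 2.5, 5, 10, 20)
  T_tot <- c(9.2e7, 9.2e7, 9.2e7, 5.7e7, 3.1e7, 1.8e7, 1.8e7)
  res <- lapply(seq_along(lags), function(i) {
    ens <- .study_run(delta_kernel(lags[i], -.STUDY$a), g$c1, g$L,
                      T_tot = T_tot[i], seed = .seed_at(seed, 20 + i))
    sl <- .slope_of(ens, g$excl, .seed_at(seed, 40 + i))
    data.frame(lag = lags[i], r = sl[["r"]], se = sl[["se"]])
  })
  out <- do.call(rbind, res)
  f <- .STUDY$a * g$c1
  out$S_norm <- out$r / f
  out$S_norm_se <- out$se / f
  tdir <- .STUDY$tau / (2 * .STUDY$p_r)
  out$S_norm_theory <- 1 - exp(-lags / tdir)
  out
}

#' Matched-geometry lag sweep at doubled run duration
#'
#' The same dimensionless geometry (box of 20 run lengths, exclusion of 4)
#' and modulation at `tau = 2 s`, for lags `T/tau` in 0.5, 2.5, 10. With
#' the normalisation of [study_lag_sweep()] the two curves must collapse
#' onto one function of `T/tau`.
#'
#' @inheritParams study_null
#' @return A data frame `lag_over_tau, S_norm, S_norm_se, S_norm_theory`.
#' @export
study_collapse_tau2 <- function(seed = 1) {
  tau <- 2
  L <- 400; excl <- 80; c1 <- 0.1125
  lot <- c(0.5, 2.5, 10)
  T_tot <- c(1.9e8, 1.2e8, 3.6e7)
  res <- lapply(seq_along(lot), function(i) {
    ens <- .study_run(delta_kernel(lot[i] * tau, -.STUDY$a), c1, L,
                      T_tot = T_tot[i], seed = .seed_at(seed, 60 + i),
                      tau = tau)
    sl <- .slope_of(ens, excl, .seed_at(seed, 70 + i))
    data.frame(lag_over_tau = lot[i], r = sl[["r"]], se = sl[["se"]])
  })
  out <- do.call(rbind, res)
  f <- .STUDY$a * c1
  out$S_norm <- out$r / f
  out$S_norm_se <- out$se / f
  out$S_norm_theory <- 1 - exp(-lot)   # tau_dir = tau at p_r = 1/2
  out
}

#' Sign antisymmetry of the slope
#'
#' Flipping the sign of the single-impulse weight must flip the sign of the
#' steady-state slope (unfavourable chemotaxis for a repellent-like
#' response). Antisymmetry is exact at linear order only -- the residual
#' sum `S(+a) + S(-a)` is second order in the modulation -- so this
#' component runs at half the standard impulse weight (max |F| = 0.05),
#' where the systematic residual is far below the statistical resolution.
#'
#' @inheritParams study_null
#' @return A list with both slopes and the antisymmetry z-score
#'   `|r_plus + r_minus| / sqrt(se+^2 + se-^2)`.
#' @export
study_sign <- function(seed = 1) {
  g <- .STUDY$M
  lag <- 1.5
  a_half <- .STUDY$a / 2
  r <- lapply(c(1, -1), function(s) {
    ens <- .study_run(delta_kernel(lag, s * a_half), g$c1, g$L,
                      T_tot = 1.1e8, seed = .seed_at(seed, 80 + s))
    .slope_of(ens, g$excl, .seed_at(seed, 84 + s))
  })
  asym <- r[[1]][["r"]] + r[[2]][["r"]]
  se <- sqrt(r[[1]][["se"]]^2 + r[[2]][["se"]]^2)
  list(lag = lag, r_plus = r[[1]][["r"]], r_plus_se = r[[1]][["se"]],
       r_minus = r[[2]][["r"]], r_minus_se = r[[2]][["se"]],
       asym = asym, asym_se = se, asym_z = asym / se)
}

#' Small-lag linearity of the slope
#'
#' In a small box (10 run lengths), the slope at lags `T <= 0.2 tau`
#' (including the measured zero-lag point) must grow linearly in `T`.
#' Resolving the 0.05 s lag grid requires `dt = tau / 20`.
#'
#' @inheritParams study_null
#' @return A list with the per-lag table, the linear fit, and its R^2.
#' @export
study_small_lag <- function(seed = 1) {
  g <- .STUDY$B
  lags <- c(0, 0.05, 0.1, 0.15, 0.2)
  res <- lapply(seq_along(lags), function(i) {
    ens <- .study_run(delta_kernel(lags[i], -.STUDY$a), g$c1, g$L,
                      T_tot = 1.9e8, seed = .seed_at(seed, 90 + i),
                      dt = 0.05)
    sl <- .slope_of(ens, g$excl, .seed_at(seed, 100 + i))
    data.frame(lag = lags[i], r = sl[["r"]], se = sl[["se"]])
  })
  tab <- do.call(rbind, res)
  fit <- stats::lm(r ~ lag, data = tab)
  list(table = tab, r_squared = summary(fit)$r.squared,
       slope_per_s = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Drift velocity: sign, exponential lag decay, spatial uniformity
#'
#' Measures the bulk drift velocity (runs starting more than 9 run lengths
#' from the walls) for a favourable single-impulse kernel at lags 0, 0.2
#' and 0.5 s. The decay ratios `v_d(T) / v_d(0)` are compared with the
#' analytic `exp(-T / tau_dir)`; the ratio cancels the common
#' finite-modulation factor. The zero-lag condition also yields the
#' spatial-uniformity chi-squared test.
#'
#' @inheritParams study_null
#' @return A list with the per-lag drift table, decay ratios and the
#'   uniformity p-value.
#' @export
study_drift <- function(seed = 1) {
  g <- .STUDY$D
  lags <- c(0, 0.2, 0.5)
  T_tot <- c(5.8e8, 3.5e8, 6.5e8)
  ests <- lapply(seq_along(lags), function(i) {
    ens <- .study_run(delta_kernel(lags[i], -.STUDY$a), g$c1, g$L,
                      T_tot = T_tot[i], seed = .seed_at(seed, 110 + i))
    estimate_drift_velocity(ens, exclusion = g$excl_t,
                            seed = .seed_at(seed, 120 + i))
  })
  tab <- data.frame(
    lag = lags,
    v_d = vapply(ests, function(e) e$v_d, 1),
    se = vapply(ests, function(e) e$se, 1)
  )
  tdir <- .STUDY$tau / (2 * .STUDY$p_r)
  ratio <- tab$v_d[-1] / tab$v_d[1]
  ratio_se <- abs(ratio) * sqrt((tab$se[-1] / tab$v_d[-1])^2 +
                                  (tab$se[1] / tab$v_d[1])^2)
  list(table = tab,
       ratio = data.frame(lag = lags[-1], ratio = ratio, se = ratio_se,
                          theory = exp(-lags[-1] / tdir)),
       uniformity_p = ests[[1]]$p_value)
}

#' Diffusivity structure across lags
#'
#' The diffusivity falls linearly with position for a non-adaptive kernel,
#' with a gradient `dD/dx = D_free c1 a` independent of the lag. This
#' component uses `dt = tau / 20`: the comparison against the linear-order
#' analytic value carries an O(10%) finite-modulation deviation, and the
#' additional discretisation bias must stay small inside the 15% band.
#'
#' @inheritParams study_null
#' @return A list with the per-lag gradient table and the analytic value.
#' @export
study_diffusivity <- function(seed = 1) {
  g <- .STUDY$D
  lags <- c(0, 0.25, 0.5)
  res <- lapply(seq_along(lags), function(i) {
    ens <- .study_run(delta_kernel(lags[i], -.STUDY$a), g$c1, g$L,
                      T_tot = 3.6e7, seed = .seed_at(seed, 210 + i),
                      dt = 0.05)
    dp <- estimate_diffusivity_profile(ens, exclusion = g$excl)
    data.frame(lag = lags[i], dDdx = dp$dDdx, dDdx_se = dp$dDdx_se,
               D0 = dp$D0)
  })
  tab <- do.call(rbind, res)
  cfg <- sim_config(v = .STUDY$v, tau = 1, dt = 0.05, p_r = .STUDY$p_r,
                    L = g$L, t_sample = 0, n_walkers = 0)
  dDdx_lin <- diffusivity_field(delta_kernel(0, -.STUDY$a), cfg,
                                conc_field(.STUDY$c0, g$c1))$dDdx
  list(table = tab, dDdx_lin_theory = dDdx_lin)
}

#' Zero-flux closure across a lag sweep
#'
#' At lags 1.5, 2.5, 3.5 s, the slope predicted from the measured transport
#' coefficients, `r_pred = (v_d - dD/dx) / D(centre)` with drift and
#' diffusivity measured in the deep bulk, is compared with the directly
#' measured slope-to-level ratio. Prediction and measurement share the
#' discrete dynamics, so the comparison is kept at `dt = tau / 20`.
#'
#' @inheritParams study_null
#' @return A data frame `lag, r_meas, se, v_d, v_d_se, dDdx, dDdx_se,
#'   r_pred, pred_se, rel_dev`.
#' @export
study_closure <- function(seed = 1) {
  g <- .STUDY$D
  lags <- c(1.5, 2.5, 3.5)
  T_tot <- c(3.7e8, 2.7e8, 2.4e8)
  res <- lapply(seq_along(lags), function(i) {
    ens <- .study_run(delta_kernel(lags[i], -.STUDY$a), g$c1, g$L,
                      T_tot = T_tot[i], seed = .seed_at(seed, 130 + i),
                      dt = 0.05)
    fit <- fit_transport(ens, exclusion = g$excl,
                         transport_exclusion = g$excl_t,
                         seed = .seed_at(seed, 140 + i))
    data.frame(
      lag = lags[i],
      r_meas = fit$closure$slope_over_level,
      se = fit$closure$slope_over_level_se,
      v_d = fit$drift$v_d, v_d_se = fit$drift$se,
      dDdx = fit$diffusivity$dDdx, dDdx_se = fit$diffusivity$dDdx_se,
      r_pred = fit$closure$predicted, pred_se = fit$closure$predicted_se,
      rel_dev = fit$closure$rel_dev
    )
  })
  do.call(rbind, res)
}

#' Superposition of impulse slopes
#'
#' Two-delta adaptive kernels `(T1, T2) = (0.2, 1)` and `(0.2, 5)`: the
#' simulated slope must equal the difference of the measured single-delta
#' slopes at `T2` and `T1`, increase with the lag separation, and be strong
#' (a large fraction of the saturated single-delta slope) when
#' `T1 << tau << T2`.
#'
#' @inheritParams study_null
#' @param sweep optional precomputed [study_lag_sweep()] table providing
#'   the single-delta references (computed if missing).
#' @return A list with the two-delta table and the superposition
#'   comparisons.
#' @export
study_superposition <- function(seed = 1, sweep = NULL) {
  g <- .STUDY$M
  if (is.null(sweep)) sweep <- study_lag_sweep(seed)
  pairs <- list(c(0.2, 1), c(0.2, 5))
  res <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    kern <- two_delta_kernel(p[1], p[2], .STUDY$a)
    ens <- .study_run(kern, g$c1, g$L, T_tot = 9.2e7,
                      seed = .seed_at(seed, 150 + i))
    sl <- .slope_of(ens, g$excl, .seed_at(seed, 160 + i))
    s1 <- sweep[sweep$lag == p[1], ]
    s2 <- sweep[sweep$lag == p[2], ]
    data.frame(T1 = p[1], T2 = p[2], r = sl[["r"]], se = sl[["se"]],
               r_pred = s2$r - s1$r, pred_se = sqrt(s1$se^2 + s2$se^2))
  })
  tab <- do.call(rbind, res)
  tab$z <- (tab$r - tab$r_pred) / sqrt(tab$se^2 + tab$pred_se^2)
  f <- .STUDY$a * g$c1
  list(table = tab,
       separation_z = (tab$r[2] - tab$r[1]) / sqrt(sum(tab$se^2)),
       strong_norm = tab$r[2] / f, strong_norm_se = tab$se[2] / f)
}

#' Bilobe kernel: optimum of the slope over the run duration
#'
#' Sweeps the mean run duration `tau` in 0.25-4 s with the packaged bilobe
#' kernel (rebalanced to exact adaptivity) at matched dimensionless
#' geometry, normalises the slope by `c1`, and locates the interior
#' maximum. Chemotaxis should be optimal for `tau` between the delays of
#' the positive and negative lobes. Time steps are the largest divisors of
#' the 0.25 s lag grid compatible with `dt <= tau / 10`, so the impulse
#' lags stay exact.
#'
#' @inheritParams study_null
#' @return A list with the per-tau table, the grid argmax, the fitted peak
#'   location `tau_star` (quadratic in `log tau`), the lobe delays, and
#'   endpoint contrasts.
#' @export
study_bilobe <- function(seed = 1) {
  kern <- bilobe_kernel()
  taus <- c(0.25, 0.5, 1, 2, 4)
  dts <- c(0.025, 0.05, 0.0625, 0.125, 0.25)
  T_tot <- c(2.9e7, 5.8e7, 1.16e8, 2.33e8, 4.7e8)
  res <- lapply(seq_along(taus), function(i) {
    tau <- taus[i]
    L <- 200 * tau
    c1 <- 45 / L
    ens <- .study_run(kern, c1, L, T_tot = T_tot[i],
                      seed = .seed_at(seed, 170 + i), tau = tau, dt = dts[i])
    sl <- .slope_of(ens, 40 * tau, .seed_at(seed, 180 + i))
    data.frame(tau = tau, r = sl[["r"]], se = sl[["se"]],
               S_norm = sl[["r"]] / c1, S_norm_se = sl[["se"]] / c1)
  })
  tab <- do.call(rbind, res)
  lt <- log(tab$tau)
  fit <- stats::lm(S_norm ~ lt + I(lt^2), data = tab)
  cf <- stats::coef(fit)
  tau_star <- if (cf[3] < 0) exp(-cf[2] / (2 * cf[3])) else NA_real_
  i_max <- which.max(tab$S_norm)
  lobe_pos <- kern$lag[which.max(kern$weight)]
  lobe_neg <- kern$lag[which.min(kern$weight)]
  list(table = tab, i_max = i_max, tau_max = tab$tau[i_max],
       tau_star = tau_star, concave = unname(cf[3] < 0),
       lobe_delays = c(positive = lobe_pos, negative = lobe_neg),
       contrast_first = (tab$S_norm[i_max] - tab$S_norm[1]) /
         sqrt(tab$S_norm_se[i_max]^2 + tab$S_norm_se[1]^2),
       contrast_last = (tab$S_norm[i_max] - tab$S_norm[nrow(tab)]) /
         sqrt(tab$S_norm_se[i_max]^2 + tab$S_norm_se[nrow(tab)]^2))
}

#' Tumble-duration insensitivity for an adaptive kernel
#'
#' With the adaptive two-delta kernel, a finite tumble duration
#' `tau_t = 0.1 tau` must leave the steady-state slope unchanged within
#' errors.
#'
#' @inheritParams study_null
#' @return A list with both slopes and the difference z-score, plus the
#'   adaptive diffusivity gradient (consistent with zero).
#' @export
study_tumble_duration <- function(seed = 1) {
  g <- .STUDY$M
  kern <- two_delta_kernel(0.5, 2, .STUDY$a)
  r <- lapply(c(0, 0.1), function(tt) {
    ens <- .study_run(kern, g$c1, g$L, T_tot = 1.1e8,
                      seed = .seed_at(seed, 190 + round(100 * tt)),
                      tau_t = tt)
    list(sl = .slope_of(ens, g$excl, .seed_at(seed, 195 + round(100 * tt))),
         ens = ens)
  })
  # adaptive diffusivity gradient from the tau_t = 0 condition
  dp <- estimate_diffusivity_profile(r[[1]]$ens, exclusion = g$excl)
  d <- r[[2]]$sl[["r"]] - r[[1]]$sl[["r"]]
  se <- sqrt(r[[1]]$sl[["se"]]^2 + r[[2]]$sl[["se"]]^2)
  list(r_tt0 = r[[1]]$sl[["r"]], se_tt0 = r[[1]]$sl[["se"]],
       r_tt1 = r[[2]]$sl[["r"]], se_tt1 = r[[2]]$sl[["se"]],
       diff = d, diff_se = se, diff_z = d / se,
       adaptive_dDdx = dp$dDdx, adaptive_dDdx_se = dp$dDdx_se)
}

#' Gradient linearity of the slope
#'
#' Doubling the attractant gradient must double the slope in the
#' weak-gradient regime.
#'
#' @inheritParams study_null
#' @param r_full optional precomputed slope at the full gradient (the
#'   lag-2.5 entry of [study_lag_sweep()]); computed if missing.
#' @return A list with both slopes, the ratio `r_full / (2 r_half)`, and
#'   the linearity z-score.
#' @export
study_gradient <- function(seed = 1, r_full = NULL) {
  g <- .STUDY$M
  lag <- 2.5
  if (is.null(r_full)) {
    ens <- .study_run(delta_kernel(lag, -.STUDY$a), g$c1, g$L,
                      T_tot = 5.7e7, seed = .seed_at(seed, 24))
    sl <- .slope_of(ens, g$excl, .seed_at(seed, 44))
    r_full <- c(r = sl[["r"]], se = sl[["se"]])
  }
  ens_h <- .study_run(delta_kernel(lag, -.STUDY$a), g$c1 / 2, g$L,
                      T_tot = 1.1e8, seed = .seed_at(seed, 200))
  sl_h <- .slope_of(ens_h, g$excl, .seed_at(seed, 201))
  d <- r_full[["r"]] - 2 * sl_h[["r"]]
  se <- sqrt(r_full[["se"]]^2 + 4 * sl_h[["se"]]^2)
  list(r_full = r_full[["r"]], r_full_se = r_full[["se"]],
       r_half = sl_h[["r"]], r_half_se = sl_h[["se"]],
       ratio = r_full[["r"]] / (2 * sl_h[["r"]]),
       diff = d, diff_se = se, linearity_z = d / se)
}

#' Run the full reduced-scale reference study
#'
#' Executes all component studies with seeds derived from one master seed,
#' sharing the single-delta lag sweep between the components that use it.
#' Takes on the order of a quarter of an hour on one CPU.
#'
#' @param seed master integer seed.
#' @param quiet suppress progress messages.
#' @return A named list with one entry per component study.
#' @export
run_acceptance_study <- function(seed = 1, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- proc.time()[["elapsed"]]
  tick <- function(what) {
    say(sprintf("[%6.1f s] %s", proc.time()[["elapsed"]] - t0, what))
  }
  tick("null model")
  null <- study_null(seed)
  tick("memoryless cancellation")
  memoryless <- study_memoryless(seed)
  tick("single-delta lag sweep")
  sweep <- study_lag_sweep(seed)
  tick("matched sweep at tau = 2")
  collapse <- study_collapse_tau2(seed)
  tick("sign antisymmetry")
  sign <- study_sign(seed)
  tick("small-lag linearity")
  small_lag <- study_small_lag(seed)
  tick("drift decay and uniformity")
  drift <- study_drift(seed)
  tick("diffusivity structure")
  diffusivity <- study_diffusivity(seed)
  tick("zero-flux closure")
  closure <- study_closure(seed)
  tick("superposition")
  superposition <- study_superposition(seed, sweep = sweep)
  tick("bilobe optimum")
  bilobe <- study_bilobe(seed)
  tick("tumble-duration insensitivity")
  tumble <- study_tumble_duration(seed)
  tick("gradient linearity")
  gradient <- study_gradient(
    seed, r_full = c(r = sweep$r[sweep$lag == 2.5],
                     se = sweep$se[sweep$lag == 2.5]))
  tick("done")
  list(null = null, memoryless = memoryless, sweep = sweep,
       collapse = collapse, sign = sign, small_lag = small_lag,
       drift = drift, diffusivity = diffusivity, closure = closure,
       superposition = superposition, bilobe = bilobe, tumble = tumble,
       gradient = gradient, seed = seed)
}
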