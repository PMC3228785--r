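# Estimators for the three observables: steady-state density slope,
# chemotactic drift velocity, and position-resolved diffusivity.
#
# Ensembles carry per-walker sufficient statistics; error bars for pooled
# estimates are obtained by bootstrap over walkers, which are exactly
# independent (positions and runs along one trajectory are strongly
# autocorrelated, so resampling at the run level would understate errors
# for the slope). For explicit run tables, the drift estimator offers a
# run-level bootstrap.

.default_exclusion <- function(config) 5 * config$v * config$tau

.retained_bins <- function(centers, L, exclusion) {
  centers > exclusion & centers < L - exclusion
}

# weighted least squares of y on x; returns c(intercept, slope) and ses
.wls <- function(x, y, w) {
  fit <- stats::lm(y ~ x, weights = w)
  list(coef = stats::coef(fit),
       se = sqrt(diag(summary(fit)$cov.unscaled) * summary(fit)$sigma^2))
}

.boot_seed <- function(seed, offset) (seed + offset) %% 2147483647

#' Estimate the steady-state density slope
#'
#' Pools the position histograms of all walkers, renormalises the density
#' over the bins retained after excluding a boundary layer at each wall,
#' and fits a weighted least-squares line. Reported quantities are the
#' density slope `S` (1/um^2, on the retained-window normalisation) and the
#' normalisation-free ratio `slope / mean level` (1/um), which is what the
#' coarse-grained theory predicts as `(v_d - dD/dx) / D`.
#'
#' Standard errors come from a seeded bootstrap over walkers; for raw
#' position input (synthetic data) the bootstrap resamples positions.
#'
#' @param x an `rt_ensemble`, or a numeric vector / list of numeric vectors
#'   of positions (one element per walker) for synthetic data.
#' @param n_bins number of histogram bins (raw-position input only; an
#'   ensemble is already binned).
#' @param exclusion boundary-layer width excluded at each wall (um);
#'   defaults to `5 * v * tau` for ensembles (0 for raw positions).
#' @param L box length; required for raw-position input.
#' @param n_boot number of bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return An object of class `density_profile`: a list with the per-bin
#'   table (`bin_x`, `P`, `P_err`), `slope`, `slope_se`,
#'   `slope_over_level`, `slope_over_level_se`, `level`, `exclusion`,
#'   `n_retained`, `n_positions`.
#' @export
estimate_density_slope <- function(x, n_bins = 20, exclusion = NULL, L = NULL,
                                   n_boot = 1000, seed = NULL) {
  if (inherits(x, "rt_ensemble")) {
    counts <- x$hist
    centers <- x$bin_centers
    L <- x$config$L
    if (is.null(exclusion)) exclusion <- .default_exclusion(x$config)
    if (is.null(seed)) seed <- x$config$seed + 1
    boot_unit <- "walker"
  } else {
    if (is.null(L)) stop("'L' is required for raw position input")
    if (is.numeric(x)) x <- list(x)
    if (!is.list(x) || !all(vapply(x, is.numeric, TRUE)))
      stop("'x' must be an rt_ensemble, a numeric vector, or a list of them")
    pos <- unlist(x, use.names = FALSE)
    if (any(pos < 0 | pos > L)) stop("positions must lie in [0, L]")
    edges <- seq(0, L, length.out = n_bins + 1)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    counts <- vapply(x, function(p)
      tabulate(pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L),
                    n_bins), nbins = n_bins), numeric(n_bins))
    counts <- matrix(counts, nrow = n_bins)
    if (is.null(exclusion)) exclusion <- 0
    if (is.null(seed)) seed <- 1
    boot_unit <- if (ncol(counts) > 1L) "walker" else "position"
  }
  keep <- .retained_bins(centers, L, exclusion)
  if (sum(keep) < 4L)
    stop("fewer than 4 bins retained after boundary exclusion")
  dx <- centers[2] - centers[1]

  fit_one <- function(cnt_pooled) {
    ck <- cnt_pooled[keep]
    if (sum(ck > 0) <= 2L) stop("degenerate histogram: positions concentrated in <= 2 bins")
    dens <- ck / (sum(ck) * dx)                # sum(P * dx) = 1 over retained
    f <- .wls(centers[keep], dens, w = 1 / pmax(ck, 1))
    c(slope = unname(f$coef[2]), level = mean(dens))
  }
  est <- fit_one(rowSums(counts))

  n_w <- ncol(counts)
  set.seed(.boot_seed(seed, 0))
  boot <- replicate(n_boot, {
    cnt <- if (boot_unit == "walker") {
      rowSums(counts[, sample.int(n_w, n_w, replace = TRUE), drop = FALSE])
    } else {
      cnt0 <- counts[, 1]
      n <- sum(cnt0)
      # multinomial resample of positions among bins
      as.numeric(stats::rmultinom(1, n, cnt0 / n))
    }
    out <- try(fit_one(cnt), silent = TRUE)
    if (inherits(out, "try-error")) c(NA_real_, NA_real_) else out
  })
  slope_se <- stats::sd(boot[1, ], na.rm = TRUE)
  sol <- est["slope"] / est["level"]
  sol_boot <- boot[1, ] / boot[2, ]
  sol_se <- stats::sd(sol_boot, na.rm = TRUE)

  cnt_pool <- rowSums(counts)[keep]
  dens <- cnt_pool / (sum(cnt_pool) * dx)
  p_err <- if (n_w > 1L) {
    per_w <- apply(counts[keep, , drop = FALSE], 2, function(ck)
      ck / pmax(sum(ck) * dx, .Machine$double.eps))
    apply(per_w, 1, stats::sd) / sqrt(n_w)
  } else {
    sqrt(pmax(cnt_pool, 1)) / (sum(cnt_pool) * dx)
  }

  structure(
    list(
      bins = data.frame(bin_x = centers[keep], P = dens, P_err = p_err),
      slope = unname(est["slope"]), slope_se = slope_se,
      slope_over_level = unname(sol), slope_over_level_se = sol_se,
      level = unname(est["level"]),
      exclusion = exclusion, L = L,
      n_retained = sum(keep), n_positions = sum(counts)
    ),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf(
    paste0("Steady-state density profile: slope S = %.4g +- %.2g 1/um^2",
           " (S / level = %.4g +- %.2g 1/um)\n  %d retained bins,",
           " exclusion %g um per wall, %.3g position samples\n"),
    x$slope, x$slope_se, x$slope_over_level, x$slope_over_level_se,
    x$n_retained, x$exclusion, x$n_positions))
  invisible(x)
}

# pull (count, sdur, sdur2, sdisp, sdisp2) matrices restricted to retained
# start-position bins from an ensemble
.run_moments <- function(ensemble, exclusion) {
  keep <- .retained_bins(ensemble$run_bin_centers, ensemble$config$L, exclusion)
  if (!any(keep)) stop("no run bins retained after boundary exclusion")
  lapply(c(ensemble$run_stats,
           list(keep = keep, centers = ensemble$run_bin_centers)),
         identity)
}

#' Estimate the chemotactic drift velocity
#'
#' The drift velocity is the mean displacement per unit time of a walker
#' starting a new run, estimated as (mean signed run displacement) / (mean
#' run duration), pooled over completed runs that start in the bulk of the
#' box (outside the boundary exclusion). Near walls, reflections both
#' truncate runs and decorrelate the direction within the memory lag, so
#' wall-layer runs are excluded; in a closed box the globally pooled ratio
#' vanishes with the net flux, and the chemotactic drift is a bulk
#' quantity.
#'
#' Per-bin estimates binned by run start position, together with a
#' chi-squared test of their mutual consistency, probe the predicted
#' spatial uniformity of the drift.
#'
#' @param x an `rt_ensemble`, or a run-summary data frame with columns
#'   `walker`, `x_start`, `duration_s`, `displacement_um`.
#' @param exclusion bulk exclusion at each wall (um); default `5 * v * tau`
#'   for ensembles. Deeper exclusions (~10 run lengths) are advisable for
#'   lags of order `tau` or larger.
#' @param L box length (run-table input only).
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed bootstrap seed.
#' @param min_runs minimal number of retained runs required.
#' @return An object of class `drift_estimate`: `v_d`, `se`, `n_runs`,
#'   per-bin table `by_bin` (`bin_x`, `v_d`, `se`, `n`), and the spatial
#'   uniformity test (`chisq`, `df`, `p_value`).
#' @export
estimate_drift_velocity <- function(x, exclusion = NULL, L = NULL,
                                    n_boot = 1000, seed = NULL,
                                    min_runs = 1000) {
  if (inherits(x, "rt_ensemble")) {
    if (is.null(exclusion)) exclusion <- .default_exclusion(x$config)
    if (is.null(seed)) seed <- x$config$seed + 2
    rm_ <- .run_moments(x, exclusion)
    keep <- rm_$keep
    cnt <- rm_$run_cnt[keep, , drop = FALSE]
    sdur <- rm_$run_sdur[keep, , drop = FALSE]
    sdisp <- rm_$run_sdisp[keep, , drop = FALSE]
    sdisp2 <- rm_$run_sdisp2[keep, , drop = FALSE]
    n_runs <- sum(cnt)
    if (n_runs < min_runs)
      stop(sprintf("too few runs (%d < %d) for a drift estimate", n_runs, min_runs))
    v_d <- sum(sdisp) / sum(sdur)
    # bootstrap over walkers
    n_w <- ncol(cnt)
    set.seed(.boot_seed(seed, 0))
    boot <- replicate(n_boot, {
      j <- sample.int(n_w, n_w, replace = TRUE)
      sum(sdisp[, j]) / sum(sdur[, j])
    })
    se <- stats::sd(boot)
    bx <- rm_$centers[keep]
    bcnt <- rowSums(cnt); bdur <- rowSums(sdur)
    bdisp <- rowSums(sdisp); bdisp2 <- rowSums(sdisp2)
    vb <- bdisp / bdur
    var_disp <- pmax(bdisp2 / bcnt - (bdisp / bcnt)^2, 0)
    seb <- sqrt(var_disp * bcnt) / bdur
    by_bin <- data.frame(bin_x = bx, v_d = vb, se = seb, n = bcnt)
  } else {
    runs <- x
    if (!is.data.frame(runs) ||
        !all(c("x_start", "duration_s", "displacement_um") %in% names(runs)))
      stop("run table must have columns x_start, duration_s, displacement_um")
    if (is.null(exclusion)) exclusion <- 0
    if (is.null(seed)) seed <- 1
    if (!is.null(L))
      runs <- runs[runs$x_start > exclusion & runs$x_start < L - exclusion, ]
    n_runs <- nrow(runs)
    if (n_runs < min_runs)
      stop(sprintf("too few runs (%d < %d) for a drift estimate", n_runs, min_runs))
    v_d <- mean(runs$displacement_um) / mean(runs$duration_s)
    set.seed(.boot_seed(seed, 0))
    boot <- replicate(n_boot, {
      j <- sample.int(n_runs, n_runs, replace = TRUE)
      mean(runs$displacement_um[j]) / mean(runs$duration_s[j])
    })
    se <- stats::sd(boot)
    if (!is.null(L)) {
      brk <- seq(exclusion, L - exclusion, length.out = 6)
      bin <- cut(runs$x_start, brk, include.lowest = TRUE)
      grp <- split(runs[, c("displacement_um", "duration_s")], bin)
      by_bin <- do.call(rbind, lapply(seq_along(grp), function(i) {
        g <- grp[[i]]
        if (nrow(g) == 0L)
          return(data.frame(bin_x = (brk[i] + brk[i + 1]) / 2,
                            v_d = NA_real_, se = NA_real_, n = 0))
        data.frame(bin_x = (brk[i] + brk[i + 1]) / 2,
                   v_d = sum(g$displacement_um) / sum(g$duration_s),
                   se = stats::sd(g$displacement_um) * sqrt(nrow(g)) /
                     sum(g$duration_s),
                   n = nrow(g))
      }))
    } else {
      by_bin <- NULL
    }
  }
  chisq <- df <- p_value <- NA_real_
  if (!is.null(by_bin) && nrow(by_bin) >= 2L) {
    ok <- by_bin$n > 0 & is.finite(by_bin$se) & by_bin$se > 0
    bb <- by_bin[ok, ]
    vbar <- sum(bb$v_d / bb$se^2) / sum(1 / bb$se^2)
    chisq <- sum((bb$v_d - vbar)^2 / bb$se^2)
    df <- nrow(bb) - 1L
    p_value <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  structure(
    list(v_d = v_d, se = se, n_runs = n_runs, by_bin = by_bin,
         chisq = chisq, df = df, p_value = p_value, exclusion = exclusion),
    class = "drift_estimate"
  )
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat(sprintf(
    "Chemotactic drift velocity: v_d = %.4g +- %.2g um/s (%.3g runs)\n",
    x$v_d, x$se, x$n_runs))
  if (is.finite(x$p_value))
    cat(sprintf("  spatial uniformity: chi^2 = %.3g on %d df, p = %.3g\n",
                x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Estimate the position-resolved diffusivity
#'
#' The local diffusivity follows the mean-free-path construction: runs are
#' binned by their start position, the mean run duration `tau_hat(x)` of
#' each retained bin gives `D_hat(x) = v^2 * tau_hat(x) / (2 * p_r)`, and a
#' weighted linear fit across bins returns the diffusivity level `D0`
#' (intercept at `x = 0`), its gradient `dD/dx`, and the value at the box
#' centre. Empty bins are dropped with a warning.
#'
#' @inheritParams estimate_drift_velocity
#' @param v,tau,p_r walker parameters (run-table input only; taken from the
#'   ensemble's configuration otherwise).
#' @return An object of class `diffusivity_profile`: per-bin table `bins`
#'   (`bin_x`, `tau_hat`, `D`, `D_err`, `n`), `D0`, `D0_se`, `dDdx`,
#'   `dDdx_se`, `D_centre`.
#' @export
estimate_diffusivity_profile <- function(x, exclusion = NULL, L = NULL,
                                         v = NULL, tau = NULL, p_r = NULL,
                                         seed = NULL) {
  if (inherits(x, "rt_ensemble")) {
    if (is.null(exclusion)) exclusion <- .default_exclusion(x$config)
    v <- x$config$v; p_r <- x$config$p_r; L <- x$config$L
    rm_ <- .run_moments(x, exclusion)
    keep <- rm_$keep
    bx <- rm_$centers[keep]
    n_b <- rowSums(rm_$run_cnt[keep, , drop = FALSE])
    sdur <- rowSums(rm_$run_sdur[keep, , drop = FALSE])
    sdur2 <- rowSums(rm_$run_sdur2[keep, , drop = FALSE])
  } else {
    runs <- x
    if (!is.data.frame(runs) ||
        !all(c("x_start", "duration_s") %in% names(runs)))
      stop("run table must have columns x_start and duration_s")
    if (is.null(L) || is.null(v) || is.null(p_r))
      stop("'L', 'v' and 'p_r' are required for run-table input")
    if (is.null(exclusion)) exclusion <- 0
    edges <- seq(exclusion, L - exclusion, length.out = 11)
    bin <- cut(runs$x_start, edges, include.lowest = TRUE)
    bx <- (edges[-1] + edges[-11]) / 2
    n_b <- as.numeric(tapply(runs$duration_s, bin, length))
    n_b[is.na(n_b)] <- 0
    sdur <- as.numeric(tapply(runs$duration_s, bin, sum))
    sdur2 <- as.numeric(tapply(runs$duration_s, bin, function(z) sum(z^2)))
    sdur[is.na(sdur)] <- 0; sdur2[is.na(sdur2)] <- 0
  }
  empty <- n_b == 0
  if (any(empty)) {
    warning(sprintf("%d empty diffusivity bin(s) dropped", sum(empty)))
    bx <- bx[!empty]; n_b <- n_b[!empty]
    sdur <- sdur[!empty]; sdur2 <- sdur2[!empty]
  }
  if (length(bx) < 2L) stop("fewer than 2 non-empty bins for the diffusivity fit")
  tau_hat <- sdur / n_b
  var_dur <- pmax(sdur2 / n_b - tau_hat^2, .Machine$double.eps)
  D <- v^2 * tau_hat / (2 * p_r)
  D_err <- v^2 / (2 * p_r) * sqrt(var_dur / n_b)
  if (any(D <= 0)) stop("non-positive diffusivity estimate; inconsistent input")
  f <- .wls(bx, D, w = 1 / D_err^2)
  D0 <- unname(f$coef[1]); dDdx <- unname(f$coef[2])
  structure(
    list(bins = data.frame(bin_x = bx, tau_hat = tau_hat, D = D,
                           D_err = D_err, n = n_b),
         D0 = D0, D0_se = unname(f$se[1]),
         dDdx = dDdx, dDdx_se = unname(f$se[2]),
         D_centre = D0 + dDdx * L / 2,
         exclusion = exclusion, L = L),
    class = "diffusivity_profile"
  )
}

#' @export
print.diffusivity_profile <- function(x, ...) {
  cat(sprintf(
    paste0("Diffusivity profile: D0 = %.4g +- %.2g um^2/s, dD/dx = %.4g +-",
           " %.2g um/s\n  (D at box centre %.4g um^2/s; %d bins, exclusion %g um)\n"),
    x$D0, x$D0_se, x$dDdx, x$dDdx_se, x$D_centre, nrow(x$bins), x$exclusion))
  invisible(x)
}
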