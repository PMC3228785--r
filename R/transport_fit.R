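# fit_transport(): the package's central fitted object. Bundles the three
# estimators and the zero-flux closure between them.

#' Fit the coarse-grained transport description to an ensemble
#'
#' Estimates the steady-state density slope, the chemotactic drift velocity
#' and the position-resolved diffusivity from a simulated ensemble, and
#' combines the transport pair into the zero-flux prediction for the slope:
#' with current `J = V P - d(D P)/dx` and `J = 0` in the closed box,
#' \deqn{S / P_0 = (v_d - dD/dx) / D.}
#' The comparison is made on the normalisation-free ratio
#' `slope / mean level` (1/um), with `D` evaluated at the box centre.
#'
#' @param ensemble an `rt_ensemble`.
#' @param exclusion boundary exclusion for the density fit (um); defaults
#'   to `5 * v * tau`.
#' @param transport_exclusion bulk exclusion for the drift and diffusivity
#'   estimators; defaults to `exclusion`. Use a deeper layer (around 10 run
#'   lengths) when kernel lags are of order `tau` or larger, since wall
#'   reflections inside the memory window suppress the measured drift.
#' @param n_boot bootstrap resamples for standard errors.
#' @param seed bootstrap seed; defaults to the ensemble seed.
#' @return An object of class `transport_fit` with components `density`
#'   ([estimate_density_slope()] result), `drift`
#'   ([estimate_drift_velocity()]), `diffusivity`
#'   ([estimate_diffusivity_profile()]), and `closure` (measured and
#'   predicted slope-to-level ratios with errors and their relative
#'   deviation).
#' @seealso [transport_theory()] for the analytic counterpart.
#' @export
fit_transport <- function(ensemble, exclusion = NULL,
                          transport_exclusion = exclusion,
                          n_boot = 1000, seed = NULL) {
  stopifnot(inherits(ensemble, "rt_ensemble"))
  if (is.null(exclusion)) exclusion <- .default_exclusion(ensemble$config)
  if (is.null(transport_exclusion)) transport_exclusion <- exclusion
  if (is.null(seed)) seed <- ensemble$config$seed

  density <- estimate_density_slope(ensemble, exclusion = exclusion,
                                    n_boot = n_boot, seed = seed + 11)
  drift <- estimate_drift_velocity(ensemble, exclusion = transport_exclusion,
                                   n_boot = n_boot, seed = seed + 12)
  diffusivity <- estimate_diffusivity_profile(ensemble,
                                              exclusion = transport_exclusion)

  r_meas <- density$slope_over_level
  r_meas_se <- density$slope_over_level_se
  num <- drift$v_d - diffusivity$dDdx
  r_pred <- num / diffusivity$D_centre
  r_pred_se <- sqrt(drift$se^2 + diffusivity$dDdx_se^2) /
    abs(diffusivity$D_centre)
  structure(
    list(
      density = density, drift = drift, diffusivity = diffusivity,
      closure = list(
        slope_over_level = r_meas, slope_over_level_se = r_meas_se,
        predicted = r_pred, predicted_se = r_pred_se,
        rel_dev = if (abs(r_meas) > 0) (r_pred - r_meas) / r_meas else NA_real_
      ),
      kernel = ensemble$kernel, field = ensemble$field,
      config = ensemble$config
    ),
    class = "transport_fit"
  )
}

#' @export
print.transport_fit <- function(x, ...) {
  cat("Coarse-grained transport fit\n")
  cat(sprintf("  slope / level      %.4g +- %.2g 1/um\n",
              x$closure$slope_over_level, x$closure$slope_over_level_se))
  cat(sprintf("  drift velocity v_d %.4g +- %.2g um/s\n",
              x$drift$v_d, x$drift$se))
  cat(sprintf("  diffusivity        D0 = %.4g +- %.2g um^2/s, dD/dx = %.4g +- %.2g um/s\n",
              x$diffusivity$D0, x$diffusivity$D0_se,
              x$diffusivity$dDdx, x$diffusivity$dDdx_se))
  cat(sprintf("  zero-flux closure  predicted %.4g +- %.2g 1/um (rel. dev. %+.1f%%)\n",
              x$closure$predicted, x$closure$predicted_se,
              100 * x$closure$rel_dev))
  invisible(x)
}

#' @export
summary.transport_fit <- function(object, ...) {
  out <- list(coef = coef(object), closure = object$closure,
              uniformity_p = object$drift$p_value,
              n_runs = object$drift$n_runs,
              n_positions = object$density$n_positions)
  class(out) <- "summary.transport_fit"
  out
}

#' @export
print.summary.transport_fit <- function(x, ...) {
  cat("Transport fit summary\n")
  print(signif(x$coef, 4))
  cat(sprintf("closure relative deviation: %+.2f%%\n", 100 * x$closure$rel_dev))
  cat(sprintf("drift spatial-uniformity p-value: %.3g\n", x$uniformity_p))
  cat(sprintf("%.3g runs, %.3g position samples\n", x$n_runs, x$n_positions))
  invisible(x)
}

#' @export
coef.transport_fit <- function(object, ...) {
  c(slope = object$density$slope,
    slope_se = object$density$slope_se,
    slope_over_level = object$closure$slope_over_level,
    slope_over_level_se = object$closure$slope_over_level_se,
    v_d = object$drift$v_d, v_d_se = object$drift$se,
    D0 = object$diffusivity$D0, D0_se = object$diffusivity$D0_se,
    dDdx = object$diffusivity$dDdx, dDdx_se = object$diffusivity$dDdx_se)
}

#' Predicted stationary density from a transport fit
#'
#' Evaluates the zero-flux predicted density line
#' `P(x) = level * (1 + r_pred * (x - x_mid))` over the retained window,
#' where `r_pred = (v_d - dD/dx) / D` from the fitted transport
#' coefficients.
#'
#' @param object a `transport_fit`.
#' @param x positions at which to evaluate; defaults to the retained bin
#'   centres.
#' @param ... unused.
#' @return A data frame with columns `x` and `P_pred`.
#' @export
predict.transport_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) x <- object$density$bins$bin_x
  xm <- mean(object$density$bins$bin_x)
  lev <- object$density$level
  data.frame(x = x, P_pred = lev * (1 + object$closure$predicted * (x - xm)))
}

#' @export
plot.transport_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  b <- x$density$bins
  graphics::plot(b$bin_x, b$P, pch = 16, xlab = "x (um)",
                 ylab = "P(x) (1/um)", main = "stationary density", ...)
  pr <- predict(x)
  graphics::lines(pr$x, pr$P_pred, col = 2, lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2, col = 2,
                   legend = "zero-flux prediction")
  d <- x$diffusivity$bins
  graphics::plot(d$bin_x, d$D, pch = 16, xlab = "x (um)",
                 ylab = "D(x) (um^2/s)", main = "diffusivity profile")
  graphics::abline(x$diffusivity$D0, x$diffusivity$dDdx, col = 2, lwd = 2)
  invisible(x)
}

#' Write transport-fit results to disk
#'
#' Emits the per-bin density profile (`density.csv`: `bin_x, P, P_err`),
#' the per-bin diffusivity profile (`diffusivity.csv`: `bin_x, D, D_err`)
#' and a summary JSON (`summary.json`) with
#' `slope, slope_err, v_d, v_d_err, D0, dDdx` and the closure quantities.
#'
#' @param fit a `transport_fit`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_transport_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "transport_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(fit$density$bins[, c("bin_x", "P", "P_err")],
                   file.path(dir, "density.csv"), row.names = FALSE)
  d <- fit$diffusivity$bins
  utils::write.csv(data.frame(bin_x = d$bin_x, D = d$D, D_err = d$D_err),
                   file.path(dir, "diffusivity.csv"), row.names = FALSE)
  s <- list(slope = fit$density$slope, slope_err = fit$density$slope_se,
            v_d = fit$drift$v_d, v_d_err = fit$drift$se,
            D0 = fit$diffusivity$D0, dDdx = fit$diffusivity$dDdx,
            slope_over_level = fit$closure$slope_over_level,
            slope_pred_over_level = fit$closure$predicted)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(s, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(paste0("{", paste(sprintf('"%s": %.15g', names(s),
                                         unlist(s)), collapse = ", "), "}"),
               file.path(dir, "summary.json"))
  }
  invisible(dir)
}
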