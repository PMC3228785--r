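# Simulation configuration, linear attractant field, and the ensemble
# driver around the compiled walker core.

#' Linear chemoattractant field
#'
#' The attractant profile is `c(x) = c0 + c1 * x`. The gradient must be
#' weak enough that the tumble-rate modulation stays in the linear-response
#' regime; [simulate_ensemble()] checks this against the kernel and warns
#' otherwise.
#'
#' @param c0 baseline concentration at `x = 0` (concentration units, >= 0).
#' @param c1 gradient (concentration units per micron; may be 0 or negative
#'   provided `c(x) >= 0` across the box).
#' @return An object of class `conc_field`.
#' @export
conc_field <- function(c0, c1 = 0) {
  if (!is.finite(c0) || !is.finite(c1)) stop("'c0' and 'c1' must be finite")
  if (c0 < 0) stop("'c0' must be non-negative")
  structure(list(c0 = c0, c1 = c1), class = "conc_field")
}

#' @export
print.conc_field <- function(x, ...) {
  cat(sprintf("Linear attractant field: c(x) = %.4g + %.4g * x\n", x$c0, x$c1))
  invisible(x)
}

#' Evaluate a linear field
#' @param field a [conc_field()].
#' @param x positions (micron).
#' @return concentrations at `x`.
#' @export
field_at <- function(field, x) field$c0 + field$c1 * x

#' Simulation configuration
#'
#' Physical and numerical parameters of the walker. Defaults are
#' E. coli-like: speed 10 um/s, mean run duration 1 s, direction-reversal
#' probability 1/2 per tumble, instantaneous tumbles, a 1 mm box. Positions
#' live on a lattice of spacing `v * dt`, so `L` must be an integer multiple
#' of `v * dt`, and the time step must satisfy `dt <= tau / 10`.
#'
#' @param v run speed (um/s).
#' @param tau mean run duration in a uniform environment (s); the base
#'   tumble probability per step is `dt / tau`.
#' @param dt time step (s), at most `tau / 10`.
#' @param p_r probability that a tumble reverses the direction of motion
#'   (0 < p_r <= 1).
#' @param L box length (um); reflecting walls at 0 and `L`.
#' @param tau_t tumble duration (s, >= 0); 0 means instantaneous tumbling.
#'   Rounded to whole steps.
#' @param response `"linear"` (default) or `"threshold_linear"`, in which
#'   the functional is replaced by zero whenever it is negative so that only
#'   favourable gradients extend runs.
#' @param n_walkers number of independent walkers in the ensemble.
#' @param t_burn burn-in time discarded before sampling (s). Defaults to
#'   `5 * L^2 / D0` with `D0 = v^2 * tau / (2 * p_r)`, the diffusive
#'   relaxation scale of the box; a warning is issued if set below
#'   `L^2 / D0`.
#' @param t_sample sampling time per walker after burn-in (s).
#' @param seed master seed (non-negative integer); per-walker streams are
#'   derived from it deterministically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(v = 10, tau = 1, dt = 0.01, p_r = 0.5, L = 1000,
                       tau_t = 0, response = c("linear", "threshold_linear"),
                       n_walkers = 50, t_burn = NULL, t_sample = 2000,
                       seed = 1L) {
  response <- match.arg(response)
  if (!is.finite(v) || v <= 0) stop("'v' must be positive")
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  if (dt > tau / 10 + 1e-12) stop("'dt' must satisfy dt <= tau / 10")
  if (!is.finite(p_r) || p_r <= 0 || p_r > 1) stop("'p_r' must be in (0, 1]")
  if (!is.finite(L) || L <= 0) stop("'L' must be positive")
  n_sites <- L / (v * dt)
  if (abs(n_sites - round(n_sites)) > 1e-8)
    stop("'L' must be an integer multiple of the lattice spacing v * dt")
  if (!is.finite(tau_t) || tau_t < 0) stop("'tau_t' must be >= 0")
  if (n_walkers < 0 || n_walkers != round(n_walkers))
    stop("'n_walkers' must be a non-negative integer")
  D0 <- v^2 * tau / (2 * p_r)
  if (is.null(t_burn)) t_burn <- 5 * L^2 / D0
  if (!is.finite(t_burn) || t_burn < 0) stop("'t_burn' must be >= 0")
  if (!is.finite(t_sample) || t_sample < 0) stop("'t_sample' must be >= 0")
  if (!is.finite(seed) || seed < 0 || seed != round(seed))
    stop("'seed' must be a non-negative integer")
  structure(
    list(v = v, tau = tau, dt = dt, p_r = p_r, L = L, tau_t = tau_t,
         response = response, n_walkers = as.integer(n_walkers),
         t_burn = t_burn, t_sample = t_sample, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("Run-and-tumble configuration: v = %g um/s, tau = %g s, dt = %g s,",
           " p_r = %g,\n  L = %g um, tau_t = %g s, response = %s,",
           " %d walker(s), burn %g s, sample %g s, seed %g\n"),
    x$v, x$tau, x$dt, x$p_r, x$L, x$tau_t, x$response, x$n_walkers,
    x$t_burn, x$t_sample, x$seed))
  invisible(x)
}

#' Free diffusivity of the unbiased walk
#'
#' The coarse-grained diffusivity of the run-and-tumble walk in a uniform
#' environment, `D0 = v^2 * tau / (2 * p_r)` (telegraph-process closed
#' form: tumbles at rate `1/tau` reverse the direction with probability
#' `p_r`, so the direction decorrelates at rate `2 * p_r / tau`).
#'
#' @param config a [sim_config()].
#' @return diffusivity in um^2/s.
#' @export
free_diffusivity <- function(config) {
  config$v^2 * config$tau / (2 * config$p_r)
}

#' Direction decorrelation time
#'
#' Time constant of the exponential decay of the direction autocorrelation,
#' `tau / (2 * p_r)`.
#'
#' @inheritParams free_diffusivity
#' @return time in seconds.
#' @export
direction_decorrelation_time <- function(config) {
  config$tau / (2 * config$p_r)
}

#' Tumble probability for one time step
#'
#' `p = clamp((dt / tau) * (1 - F), 0, 1)`. In threshold-linear mode the
#' functional is first replaced by `max(F, 0)`, so an unfavourable
#' (negative) functional leaves the base rate unchanged while a favourable
#' one still extends runs.
#'
#' @param F memory functional value(s).
#' @param dt time step (s).
#' @param tau mean run duration (s).
#' @param response `"linear"` or `"threshold_linear"`.
#' @return tumble probability in `[0, 1]`, vectorised over `F`.
#' @export
tumble_probability <- function(F, dt, tau, response = c("linear", "threshold_linear")) {
  response <- match.arg(response)
  if (dt <= 0 || tau <= 0) stop("'dt' and 'tau' must be positive")
  if (response == "threshold_linear") F <- pmax(F, 0)
  pmin(pmax((dt / tau) * (1 - F), 0), 1)
}

#' Reflect a position off the box walls
#'
#' Mirrors a position that has overshot the box `[0, L]` back inside and
#' flips the direction of motion; positions inside the box are unchanged.
#' The walker's concentration history is not touched by reflection. An
#' overshoot beyond one step length signals an inconsistent lattice and is
#' an error.
#'
#' @param x position(s), allowed to exceed the box by at most `step`.
#' @param direction direction(s) of motion, `+1` or `-1`.
#' @param L box length.
#' @param step maximal legal overshoot (one lattice step `v * dt`); `Inf`
#'   disables the check.
#' @return A list with reflected `x` and `direction`.
#' @export
apply_reflection <- function(x, direction, L, step = Inf) {
  if (any(x < -step) || any(x > L + step))
    stop("position overshoots the box by more than one step; ",
         "inconsistent lattice or time step")
  hi <- x > L
  lo <- x < 0
  x[hi] <- 2 * L - x[hi]
  x[lo] <- -x[lo]
  direction[hi | lo] <- -direction[hi | lo]
  list(x = x, direction = direction)
}

#' Check the weak-gradient (linear-response) condition
#'
#' Bounds the memory functional by `sum(|a_i|) * max c(x)` over the box and
#' compares it with `threshold`. In the linear model the theory and the
#' linearity of the response hold only for small modulations.
#'
#' @param kernel a [response_kernel()].
#' @param field a [conc_field()].
#' @param config a [sim_config()].
#' @param threshold warning threshold for the modulation bound.
#' @return The modulation bound, invisibly; warns if it exceeds `threshold`.
#' @export
check_weak_gradient <- function(kernel, field, config, threshold = 0.25) {
  cmax <- max(field_at(field, 0), field_at(field, config$L))
  bound <- sum(abs(kernel$weight)) * cmax
  if (bound > threshold)
    warning(sprintf(
      "modulation bound sum|a_i| * max c = %.3g exceeds %.3g; linear response may fail",
      bound, threshold))
  invisible(bound)
}

#' Simulate an ensemble of independent walkers
#'
#' Evolves `config$n_walkers` independent non-interacting walkers in the
#' reflecting box under the discrete-time law of motion: each step a running
#' walker translates by `v * dt`, reflects off walls, appends the local
#' concentration to its history, evaluates the memory functional and
#' tumbles with probability [tumble_probability()]. A tumble reverses the
#' direction with probability `p_r` and, when `tau_t > 0`, suspends
#' translation for `round(tau_t / dt)` steps. Memory is never reset at
#' tumbles or reflections. Each walker starts at an independent uniform
#' lattice position with a random direction, is burned in for `t_burn`, and
#' is then sampled for `t_sample`.
#'
#' For large ensembles the function returns per-walker sufficient
#' statistics: a position histogram over the sampling window and per-bin
#' moments (count, duration, squared duration, displacement, squared
#' displacement) of the completed runs, binned by run start position. Set
#' `record_runs` / `record_steps` to also keep the full run table and the
#' per-step trajectory (small runs only).
#'
#' @param kernel a [response_kernel()].
#' @param field a [conc_field()].
#' @param config a [sim_config()].
#' @param n_bins number of position histogram bins across the box.
#' @param n_bins_run number of start-position bins for run statistics.
#' @param record_runs keep one row per completed run
#'   (`walker, t_start, x_start, duration_s, displacement_um`).
#' @param record_steps keep one row per step
#'   (`walker, t, x, dir, tumbled, F`); refused for runs longer than
#'   2e7 total steps.
#' @param check_gradient logical; warn when the weak-gradient bound is
#'   violated.
#' @return An object of class `rt_ensemble`.
#' @export
simulate_ensemble <- function(kernel, field, config, n_bins = 50,
                              n_bins_run = 20, record_runs = FALSE,
                              record_steps = FALSE, check_gradient = TRUE) {
  stopifnot(inherits(kernel, "response_kernel"),
            inherits(field, "conc_field"),
            inherits(config, "sim_config"))
  if (field_at(field, 0) < 0 || field_at(field, config$L) < 0)
    stop("concentration must be non-negative across the box")
  if (check_gradient) check_weak_gradient(kernel, field, config)
  D0 <- free_diffusivity(config)
  if (config$t_burn < config$L^2 / D0)
    warning(sprintf(
      "burn-in %.3g s is shorter than the diffusive relaxation scale L^2/D0 = %.3g s",
      config$t_burn, config$L^2 / D0))

  lag_steps <- .lag_steps(kernel$lag, config$dt)
  burn_steps <- round(config$t_burn / config$dt)
  sample_steps <- round(config$t_sample / config$dt)
  tumble_steps <- as.integer(round(config$tau_t / config$dt))
  if (record_steps &&
      (burn_steps + sample_steps) * max(config$n_walkers, 1) > 2e7)
    stop("'record_steps' is only supported for small simulations")

  res <- .rt_core(
    lag_steps = lag_steps, weights = kernel$weight,
    v = config$v, tau = config$tau, dt = config$dt, p_r = config$p_r,
    L = config$L, tumble_steps = tumble_steps,
    threshold = identical(config$response, "threshold_linear"),
    c0 = field$c0, c1 = field$c1, n_walkers = config$n_walkers,
    burn_steps_d = burn_steps, sample_steps_d = sample_steps,
    n_bins_hist = as.integer(n_bins), n_bins_run = as.integer(n_bins_run),
    seed_d = config$seed, record_runs = record_runs,
    record_steps = record_steps
  )
  structure(
    list(
      hist = res$hist,
      bin_centers = (seq_len(n_bins) - 0.5) * config$L / n_bins,
      bin_width = config$L / n_bins,
      run_bin_centers = (seq_len(n_bins_run) - 0.5) * config$L / n_bins_run,
      run_stats = res[c("run_cnt", "run_sdur", "run_sdur2",
                        "run_sdisp", "run_sdisp2")],
      walker_stats = res[c("w_nruns", "w_sdur", "w_sdur2",
                           "w_sdisp", "w_sdisp2")],
      x0 = res$x0, dir0 = res$dir0,
      runs = if (record_runs) res$runs else NULL,
      steps = if (record_steps) res$steps else NULL,
      kernel = kernel, field = field, config = config
    ),
    class = "rt_ensemble"
  )
}

#' @export
print.rt_ensemble <- function(x, ...) {
  cat(sprintf(
    "Run-and-tumble ensemble: %d walker(s), %.3g runs sampled over %.3g s each\n",
    x$config$n_walkers, sum(x$walker_stats$w_nruns), x$config$t_sample))
  cat(sprintf("  kernel: %d impulse(s), %s; field c(x) = %.3g + %.3g x; box %g um\n",
              length(x$kernel$lag),
              if (x$kernel$adaptive) "adaptive" else "non-adaptive",
              x$field$c0, x$field$c1, x$config$L))
  invisible(x)
}

#' Run an ensemble and return full trajectory records
#'
#' Convenience wrapper around [simulate_ensemble()] with per-step and
#' per-run recording, returning one trajectory record per walker. Intended
#' for small simulations; use [simulate_ensemble()] for production
#' ensembles.
#'
#' @inheritParams simulate_ensemble
#' @return A list with one element per walker, each a list with fields
#'   `walker`, `steps` (data frame `t, x, dir, tumbled, F`) and `runs`
#'   (data frame `t_start, x_start, duration_s, displacement_um`).
#' @export
run_ensemble <- function(kernel, field, config, check_gradient = TRUE) {
  if (config$n_walkers == 0L) return(list())
  ens <- simulate_ensemble(kernel, field, config,
                           record_runs = TRUE, record_steps = TRUE,
                           check_gradient = check_gradient)
  lapply(seq_len(config$n_walkers), function(w) {
    list(
      walker = w,
      steps = ens$steps[ens$steps$walker == w,
                        c("t", "x", "dir", "tumbled", "F"), drop = FALSE],
      runs = ens$runs[ens$runs$walker == w,
                      c("t_start", "x_start", "duration_s", "displacement_um"),
                      drop = FALSE]
    )
  })
}

#' Write trajectory and run-summary tables to CSV
#'
#' Writes `trajectories.csv` (`t, walker, x, dir, tumbled`) and
#' `runs.csv` (`walker, t_start, duration_s, displacement_um`) for an
#' ensemble simulated with recording enabled.
#'
#' @param ensemble an `rt_ensemble` with `record_steps`/`record_runs` data.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_trajectories <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "rt_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(ensemble$steps)) {
    utils::write.csv(
      ensemble$steps[, c("t", "walker", "x", "dir", "tumbled")],
      file.path(dir, "trajectories.csv"), row.names = FALSE)
  }
  if (!is.null(ensemble$runs)) {
    utils::write.csv(
      ensemble$runs[, c("walker", "t_start", "duration_s", "displacement_um")],
      file.path(dir, "runs.csv"), row.names = FALSE)
  }
  invisible(dir)
}
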