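# Experiment orchestration: parameter sweeps joining simulation with
# theory, and deterministic fixture generation.

#' Define a sweep experiment
#'
#' An experiment evaluates, at every grid point of a swept variable and for
#' each replicate, a simulated ensemble together with the transport fit and
#' the analytic theory, and joins them in one results table.
#'
#' @param name experiment name (used in output files).
#' @param kernel a [response_kernel()], or a function `value -> kernel`
#'   when the sweep variable parametrises the kernel (e.g. the impulse lag).
#' @param field a [conc_field()], or a function `value -> conc_field`.
#' @param config a [sim_config()], or a function `value -> sim_config`.
#' @param sweep list with `var` (a label for the swept variable) and
#'   `grid` (non-empty, strictly increasing numeric grid).
#' @param replicates replicates per grid point (independent seeds).
#' @param seed master seed; grid-point seeds are derived from it.
#' @param out_dir optional output directory for `results.csv` and a
#'   provenance file.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, kernel, field, config,
                            sweep = list(var = "lag", grid = numeric(0)),
                            replicates = 1, seed = 1, out_dir = NULL) {
  if (!is.list(sweep) || is.null(sweep$var) || is.null(sweep$grid))
    stop("'sweep' must be a list with fields 'var' and 'grid'")
  grid <- as.numeric(sweep$grid)
  if (length(grid) == 0L) stop("sweep grid must be non-empty")
  if (any(diff(grid) <= 0)) stop("sweep grid must be strictly increasing")
  ok_kernel <- inherits(kernel, "response_kernel") || is.function(kernel)
  if (!ok_kernel) stop("'kernel' must be a response_kernel or a function")
  if (!(inherits(field, "conc_field") || is.function(field)))
    stop("'field' must be a conc_field or a function")
  if (!(inherits(config, "sim_config") || is.function(config)))
    stop("'config' must be a sim_config or a function")
  if (replicates < 1 || replicates != round(replicates))
    stop("'replicates' must be a positive integer")
  structure(
    list(name = name, kernel = kernel, field = field, config = config,
         sweep = list(var = sweep$var, grid = grid),
         replicates = as.integer(replicates), seed = seed,
         out_dir = out_dir),
    class = "experiment_spec"
  )
}

.materialise <- function(x, value) if (is.function(x)) x(value) else x

#' Run a sweep experiment
#'
#' For each grid point and replicate, simulates the ensemble, fits the
#' transport description ([fit_transport()]) and evaluates the analytic
#' theory ([transport_theory()]); results are joined into one data frame
#' with simulated and theoretical columns and their relative deviation.
#' Deterministic given the spec (per-point seeds derive from the master
#' seed).
#'
#' @param spec an [experiment_spec()].
#' @param exclusion,transport_exclusion passed to [fit_transport()].
#' @param n_bins,n_bins_run passed to [simulate_ensemble()].
#' @param quiet suppress progress messages.
#' @return A data frame, one row per grid point and replicate, with columns
#'   `name, var, value, replicate, seed, slope_sim, slope_sim_se,
#'   slope_theory, rel_dev_slope, vd_sim, vd_sim_se, vd_theory, D0_sim,
#'   dDdx_sim, dDdx_sim_se, dDdx_theory` (slopes as slope-to-level ratios,
#'   1/um).
#' @export
run_experiment <- function(spec, exclusion = NULL, transport_exclusion = NULL,
                           n_bins = 50, n_bins_run = 20, quiet = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (!is.null(spec$out_dir)) {
    if (!dir.exists(spec$out_dir))
      dir.create(spec$out_dir, recursive = TRUE)
    if (file.access(spec$out_dir, mode = 2) != 0)
      stop("output directory is not writable: ", spec$out_dir)
  }
  rows <- list()
  prov <- character(0)
  k <- 0L
  for (i in seq_along(spec$sweep$grid)) {
    value <- spec$sweep$grid[i]
    for (rep in seq_len(spec$replicates)) {
      k <- k + 1L
      kernel <- .materialise(spec$kernel, value)
      field <- .materialise(spec$field, value)
      config <- .materialise(spec$config, value)
      seed_i <- (spec$seed + 9973 * (k - 1L)) %% 2147483647
      config$seed <- seed_i
      if (!quiet)
        message(sprintf("[%s] %s = %g (replicate %d, seed %d)",
                        spec$name, spec$sweep$var, value, rep, seed_i))
      ens <- simulate_ensemble(kernel, field, config, n_bins = n_bins,
                               n_bins_run = n_bins_run)
      fit <- fit_transport(ens, exclusion = exclusion,
                           transport_exclusion = transport_exclusion)
      th <- transport_theory(kernel, config, field)
      rows[[k]] <- data.frame(
        name = spec$name, var = spec$sweep$var, value = value,
        replicate = rep, seed = seed_i,
        slope_sim = fit$closure$slope_over_level,
        slope_sim_se = fit$closure$slope_over_level_se,
        slope_theory = th$slope_over_level,
        rel_dev_slope = if (th$slope_over_level != 0)
          fit$closure$slope_over_level / th$slope_over_level - 1 else NA_real_,
        vd_sim = fit$drift$v_d, vd_sim_se = fit$drift$se,
        vd_theory = th$v_d,
        D0_sim = fit$diffusivity$D0,
        dDdx_sim = fit$diffusivity$dDdx,
        dDdx_sim_se = fit$diffusivity$dDdx_se,
        dDdx_theory = th$dDdx
      )
      prov <- c(prov, sprintf(
        "point: %d\nvar: %s\nvalue: %g\nreplicate: %d\nseed: %d\n%s%s%s",
        k, spec$sweep$var, value, rep, seed_i,
        .flat_config(config), .flat_field(field), .flat_kernel(kernel)))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(spec$out_dir)) {
    utils::write.csv(out, file.path(spec$out_dir,
                                    paste0(spec$name, "_results.csv")),
                     row.names = FALSE)
    writeLines(paste(prov, collapse = "\n---\n"),
               file.path(spec$out_dir, paste0(spec$name, "_provenance.txt")))
  }
  out
}

.flat_config <- function(config) {
  paste0(paste(sprintf("config.%s: %g",
                       c("v", "tau", "dt", "p_r", "L", "tau_t", "n_walkers",
                         "t_burn", "t_sample", "seed"),
                       c(config$v, config$tau, config$dt, config$p_r,
                         config$L, config$tau_t, config$n_walkers,
                         config$t_burn, config$t_sample, config$seed)),
               collapse = "\n"),
         "\nconfig.response: ", config$response, "\n")
}

.flat_field <- function(field) {
  sprintf("field.c0: %g\nfield.c1: %g\n", field$c0, field$c1)
}

.flat_kernel <- function(kernel) {
  paste0("kernel.lag_s: ", paste(kernel$lag, collapse = ","),
         "\nkernel.weight: ", paste(kernel$weight, collapse = ","), "\n")
}

#' Sweep the impulse lag of a single-delta kernel
#'
#' @param weight impulse amplitude.
#' @param grid lags to sweep (s).
#' @param field a [conc_field()].
#' @param config a [sim_config()].
#' @param ... passed to [experiment_spec()].
#' @return An [experiment_spec()].
#' @export
sweep_lag <- function(weight, grid, field, config, ...) {
  experiment_spec(name = "lag_sweep",
                  kernel = function(Tlag) delta_kernel(Tlag, weight),
                  field = field, config = config,
                  sweep = list(var = "lag", grid = grid), ...)
}

#' Sweep the mean run duration at fixed kernel
#'
#' The time step is scaled with `tau` (`dt = tau / 20`) and the burn-in is
#' left at its diffusive default for each grid point.
#'
#' @param kernel a [response_kernel()] (fixed across the sweep).
#' @param grid run durations to sweep (s).
#' @param field a [conc_field()].
#' @param base_config a [sim_config()] providing all other parameters.
#' @param ... passed to [experiment_spec()].
#' @return An [experiment_spec()].
#' @export
sweep_tau <- function(kernel, grid, field, base_config, ...) {
  experiment_spec(
    name = "tau_sweep", kernel = kernel, field = field,
    config = function(tau) {
      sim_config(v = base_config$v, tau = tau, dt = tau / 20,
                 p_r = base_config$p_r, L = base_config$L,
                 tau_t = base_config$tau_t, response = base_config$response,
                 n_walkers = base_config$n_walkers,
                 t_sample = base_config$t_sample, seed = base_config$seed)
    },
    sweep = list(var = "tau", grid = grid), ...)
}

#' Generate deterministic fixture files
#'
#' Writes small plain-text fixtures used by the estimator tests and by
#' downstream analyses:
#' \itemize{
#'   \item `bilobe_fixture.csv` -- the packaged synthetic bilobe kernel
#'     table;
#'   \item `synthetic_positions.csv` -- positions drawn from a known linear
#'     density (columns `walker, x`; planted slope recorded in the header
#'     comment);
#'   \item `synthetic_runs.csv` -- a run summary drawn from a known drift
#'     law (exponential durations, signed displacements with a planted
#'     direction bias);
#'   \item `golden_theory.json` -- analytic transport quantities for a grid
#'     of single-delta kernels (requires the `jsonlite` package).
#' }
#' Byte-identical across calls with the same seed.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list with the planted ground-truth values.
#' @export
generate_fixtures <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)

  # 1. kernel table
  write_kernel(bilobe_kernel(rebalance = FALSE),
               file.path(dir, "bilobe_fixture.csv"),
               comment = "synthetic discretised bilobe response kernel")

  # 2. positions from P(x) = (1 + s * (x - L/2)) / L on [0, L]
  L <- 200; s <- 2e-3; n <- 5000; n_w <- 10
  u <- stats::runif(n)
  # inverse CDF of the linear density
  a <- s / 2
  xr <- (-(1 - a * L) + sqrt((1 - a * L)^2 + 4 * a * L * u)) / (2 * a)
  pos <- data.frame(walker = rep(seq_len(n_w), each = n / n_w),
                    x = round(xr * 1, 6))
  fp <- file.path(dir, "synthetic_positions.csv")
  con <- file(fp, "w")
  writeLines(sprintf(
    "# synthetic positions from planted linear density: L=%g, slope/level=%g",
    L, s), con)
  writeLines("walker,x", con)
  writeLines(sprintf("%d,%.6f", pos$walker, pos$x), con)
  close(con)

  # 3. runs with planted drift: P(dir=+1) = (1 + b)/2, duration ~ Exp(tau)
  tau <- 1; v <- 10; b <- 0.02; n_runs <- 4000
  dur <- round(stats::rexp(n_runs, 1 / tau), 6)
  dirs <- ifelse(stats::runif(n_runs) < (1 + b) / 2, 1, -1)
  runs <- data.frame(walker = rep(seq_len(8), length.out = n_runs),
                     t_start = round(cumsum(dur) - dur, 6),
                     x_start = round(stats::runif(n_runs, 0, L), 6),
                     duration_s = dur,
                     displacement_um = round(dirs * v * dur, 6))
  fr <- file.path(dir, "synthetic_runs.csv")
  con <- file(fr, "w")
  writeLines(sprintf(
    "# synthetic run summary with planted drift v_d = b*v = %g um/s", b * v),
    con)
  writeLines("walker,t_start,x_start,duration_s,displacement_um", con)
  writeLines(sprintf("%d,%.6f,%.6f,%.6f,%.6f", runs$walker, runs$t_start,
                     runs$x_start, runs$duration_s, runs$displacement_um),
             con)
  close(con)

  # 4. golden analytic theory values
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- sim_config(v = 10, tau = 1, dt = 0.05, p_r = 0.5, L = 200,
                      t_sample = 0, seed = seed)
    fld <- conc_field(5, 0.1)
    grid <- c(0, 0.5, 1, 2, 5)
    golden <- lapply(grid, function(Tlag) {
      th <- transport_theory(delta_kernel(Tlag, -0.002), cfg, fld)
      list(lag = Tlag, v_d = th$v_d, D0 = th$D0, dDdx = th$dDdx,
           slope = th$slope)
    })
    jsonlite::write_json(golden, file.path(dir, "golden_theory.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    warning("jsonlite not available; golden_theory.json not written")
  }
  invisible(list(L = L, planted_slope_over_level = s, planted_vd = b * v,
                 tau = tau, v = v))
}
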