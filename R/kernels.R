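# Response kernels as weighted sums of delta impulses, and the linear
# memory functional they define over a concentration history.

#' Construct a response kernel from impulse lags and weights
#'
#' A response kernel encodes how the concentration experienced at past times
#' modulates the present tumble probability. It is represented as a discrete
#' set of impulses: lags \eqn{T_i \ge 0} (seconds) and amplitudes \eqn{a_i}
#' (per concentration unit), so the memory functional is
#' \eqn{F(t) = \sum_i a_i c(x(t - T_i))}. A kernel is classified as
#' *adaptive* when its total weight vanishes (relative to the total absolute
#' weight), which makes behaviour insensitive to the absolute concentration
#' level.
#'
#' @param lag numeric vector of non-negative lags, in seconds.
#' @param weight numeric vector of impulse amplitudes, same length as `lag`.
#' @param adaptive_tol relative tolerance used to classify the kernel as
#'   adaptive: adaptive iff `|sum(weight)| <= adaptive_tol * sum(abs(weight))`.
#' @return An object of class `response_kernel` with fields `lag`, `weight`,
#'   `max_lag`, `adaptive` and `adaptive_tol`.
#' @seealso [delta_kernel()], [two_delta_kernel()], [bilobe_kernel()],
#'   [evaluate_functional()]
#' @export
response_kernel <- function(lag, weight, adaptive_tol = 1e-2) {
  lag <- as.numeric(lag)
  weight <- as.numeric(weight)
  if (length(lag) == 0L) stop("kernel must contain at least one impulse")
  if (length(lag) != length(weight))
    stop("'lag' and 'weight' must have the same length")
  if (any(!is.finite(lag)) || any(lag < 0))
    stop("impulse lags must be finite and non-negative")
  if (any(!is.finite(weight))) stop("impulse weights must be finite")
  if (!is.numeric(adaptive_tol) || adaptive_tol < 0)
    stop("'adaptive_tol' must be a non-negative number")
  structure(
    list(
      lag = lag,
      weight = weight,
      max_lag = max(lag),
      adaptive = .is_adaptive(weight, adaptive_tol),
      adaptive_tol = adaptive_tol
    ),
    class = "response_kernel"
  )
}

.is_adaptive <- function(weight, tol) {
  abs(sum(weight)) <= tol * sum(abs(weight))
}

#' Singular (single-delta) response kernel
#'
#' The memoryless limit `lag = 0` reproduces the classical drift
#' calculation in which a bacterium responds only to the instantaneous
#' concentration; a zero `weight` gives the null kernel, for which the
#' walk reduces to an unbiased run-and-tumble process.
#'
#' @param lag lag of the impulse (seconds, `>= 0`).
#' @param weight impulse amplitude (may be negative or zero).
#' @inheritParams response_kernel
#' @return A `response_kernel` with one impulse.
#' @examples
#' delta_kernel(0, 0.002)    # memoryless, non-adaptive
#' delta_kernel(5, 0)        # null kernel: F is identically zero
#' @export
delta_kernel <- function(lag, weight, adaptive_tol = 1e-2) {
  if (length(lag) != 1L || length(weight) != 1L)
    stop("'lag' and 'weight' must be scalars")
  if (!is.finite(lag) || lag < 0) stop("'lag' must be finite and >= 0")
  response_kernel(lag, weight, adaptive_tol = adaptive_tol)
}

#' Two-delta adaptive response kernel
#'
#' The toy adaptive kernel `a * (delta(t - T1) - delta(t - T2))`: a positive
#' impulse at the earlier lag and an equal negative impulse at the later
#' lag, so the total weight vanishes exactly. Strong chemotaxis occurs when
#' `T1` is much smaller and `T2` much larger than the mean run duration.
#'
#' @param T1 earlier lag (seconds), must satisfy `T1 < T2`.
#' @param T2 later lag (seconds).
#' @param a common amplitude (`> 0`).
#' @inheritParams response_kernel
#' @return An adaptive `response_kernel` with impulses `(T1, +a), (T2, -a)`.
#' @export
two_delta_kernel <- function(T1, T2, a, adaptive_tol = 1e-2) {
  if (!is.finite(T1) || !is.finite(T2) || T1 < 0)
    stop("lags must be finite and non-negative")
  if (T1 >= T2) stop("'T1' must be strictly smaller than 'T2'")
  if (!is.finite(a) || a <= 0) stop("'a' must be a positive amplitude")
  response_kernel(c(T1, T2), c(a, -a), adaptive_tol = adaptive_tol)
}

#' Discretised bilobe response kernel
#'
#' A tabulated kernel with an early positive lobe and a shallower negative
#' lobe extending to later lags, mimicking the shape of the measured
#' wild-type *E. coli* response to an attractant impulse. The packaged
#' default table (`bilobe_fixture.csv`) is a synthetic discretisation with
#' that qualitative shape -- positive peak near 0.5 s, zero crossing near
#' 1 s, negative lobe out to 3.5 s, total area close to zero; it does not
#' reproduce any particular measured amplitudes. Because the raw area is
#' only close to zero, `rebalance = TRUE` (default) applies a uniform
#' additive correction to the weights so that they sum to zero exactly,
#' enforcing adaptivity.
#'
#' @param table a data frame with columns `lag_s` and `weight` (lags
#'   strictly increasing), or `NULL` to use the packaged fixture table.
#' @param rebalance logical; subtract the mean weight so the total weight
#'   is exactly zero.
#' @inheritParams response_kernel
#' @return A `response_kernel`.
#' @export
bilobe_kernel <- function(table = NULL, rebalance = TRUE, adaptive_tol = 1e-2) {
  if (is.null(table)) table <- bilobe_table()
  if (!is.data.frame(table) || !all(c("lag_s", "weight") %in% names(table)))
    stop("'table' must be a data frame with columns 'lag_s' and 'weight'")
  if (nrow(table) == 0L) stop("kernel table is empty")
  lag <- as.numeric(table$lag_s)
  w <- as.numeric(table$weight)
  if (any(diff(lag) <= 0)) stop("kernel lags must be strictly increasing")
  if (rebalance) w <- w - mean(w)
  response_kernel(lag, w, adaptive_tol = adaptive_tol)
}

#' The packaged bilobe kernel table
#'
#' Returns the synthetic discretised bilobe table shipped with the package
#' (also available as the plain-text file `bilobe_fixture.csv` under
#' `inst/extdata`).
#'
#' @return A data frame with columns `lag_s` and `weight`.
#' @export
bilobe_table <- function() {
  path <- system.file("extdata", "bilobe_fixture.csv", package = "runtumble")
  if (!nzchar(path)) stop("packaged bilobe fixture not found")
  read_kernel_table(path)
}

#' Read / write a kernel table as CSV
#'
#' The on-disk format is a two-column CSV with header `lag_s,weight`;
#' lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_kernel_table()` returns a data frame with columns `lag_s`
#'   and `weight`; `read_kernel()` additionally builds the kernel.
#' @export
read_kernel_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("lag_s", "weight") %in% names(tab)))
    stop("kernel file must have columns 'lag_s' and 'weight': ", path)
  tab[, c("lag_s", "weight")]
}

#' @rdname read_kernel_table
#' @inheritParams bilobe_kernel
#' @export
read_kernel <- function(path, rebalance = FALSE, adaptive_tol = 1e-2) {
  tab <- read_kernel_table(path)
  if (rebalance) {
    bilobe_kernel(tab, rebalance = TRUE, adaptive_tol = adaptive_tol)
  } else {
    response_kernel(tab$lag_s, tab$weight, adaptive_tol = adaptive_tol)
  }
}

#' @rdname read_kernel_table
#' @param kernel a `response_kernel`.
#' @param comment optional comment line written at the top of the file.
#' @export
write_kernel <- function(kernel, path, comment = NULL) {
  stopifnot(inherits(kernel, "response_kernel"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("lag_s,weight", con)
  writeLines(sprintf("%.10g,%.10g", kernel$lag, kernel$weight), con)
  invisible(path)
}

#' Is a kernel adaptive?
#'
#' A kernel is adaptive when the total area under the response curve
#' vanishes, i.e. the impulse weights sum to zero within a relative
#' tolerance. Adaptive kernels are insensitive to a uniform offset of the
#' concentration field.
#'
#' @param kernel a `response_kernel`.
#' @param tol relative tolerance; defaults to the tolerance stored in the
#'   kernel.
#' @return logical.
#' @export
is_adaptive <- function(kernel, tol = kernel$adaptive_tol) {
  stopifnot(inherits(kernel, "response_kernel"))
  .is_adaptive(kernel$weight, tol)
}

#' Linear combination of response kernels
#'
#' Concatenates the impulses of two kernels with multipliers, exploiting
#' the linearity of the memory functional.
#'
#' @param k1,k2 `response_kernel` objects.
#' @param w1,w2 scalar multipliers.
#' @inheritParams response_kernel
#' @return A `response_kernel` whose functional is
#'   `w1 * F_k1 + w2 * F_k2` on any history.
#' @export
combine_kernels <- function(k1, k2, w1 = 1, w2 = 1, adaptive_tol = 1e-2) {
  stopifnot(inherits(k1, "response_kernel"), inherits(k2, "response_kernel"))
  response_kernel(c(k1$lag, k2$lag), c(w1 * k1$weight, w2 * k2$weight),
                  adaptive_tol = adaptive_tol)
}

#' @export
print.response_kernel <- function(x, ...) {
  cat(sprintf(
    "Response kernel: %d impulse(s), max lag %.3g s, %s (sum %.3g, sum|.| %.3g)\n",
    length(x$lag), x$max_lag,
    if (x$adaptive) "adaptive" else "non-adaptive",
    sum(x$weight), sum(abs(x$weight))
  ))
  n <- min(length(x$lag), 12L)
  tab <- data.frame(lag_s = x$lag[seq_len(n)], weight = x$weight[seq_len(n)])
  print(tab, row.names = FALSE)
  if (length(x$lag) > n) cat("  ...", length(x$lag) - n, "more impulses\n")
  invisible(x)
}

# Lags are mapped to whole time steps by round-half-up, so a lag exactly
# between two steps goes to the later step. Keeping one fixed rule makes the
# two-delta difference exact when T2 - T1 is a multiple of dt.
.lag_steps <- function(lag, dt) {
  # small epsilon so that decimal inputs sitting numerically just below a
  # half-step (e.g. 0.15 / 0.1) still round up as documented
  as.integer(floor(lag / dt + 0.5 + 1e-8))
}

#' Concentration history of a walker
#'
#' The sequence of concentrations experienced by a walker at each past time
#' step, aligned to the simulation clock. Queries at lags reaching before
#' the first recorded step return `fill`, the concentration at the walker's
#' initial position (equivalent to assuming the walker sat at its start
#' point before the simulation began).
#'
#' @param values numeric vector of concentrations, oldest first; one entry
#'   per time step.
#' @param dt time step (seconds).
#' @param fill pre-history fill value; defaults to the first entry.
#' @return An object of class `concentration_history`.
#' @export
concentration_history <- function(values, dt, fill = values[1L]) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("history must contain at least one value")
  if (any(!is.finite(values)) || any(values < 0))
    stop("concentrations must be finite and non-negative")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  structure(list(values = values, dt = dt, fill = fill),
            class = "concentration_history")
}

#' Evaluate the memory functional
#'
#' Computes \eqn{F = \sum_i a_i\, c(x(t - T_i))} on a recorded
#' concentration history, with lags rounded to the nearest whole time step
#' (ties round up). Queries that reach before the start of the history
#' return the history's fill value. The result is exact once the history is
#' at least `ceiling(max_lag / dt)` steps long.
#'
#' @param kernel a `response_kernel`.
#' @param history a [concentration_history()].
#' @param now index of the current time step within the history; defaults
#'   to the most recent entry.
#' @return The dimensionless functional value `F`.
#' @export
evaluate_functional <- function(kernel, history, now = length(history$values)) {
  stopifnot(inherits(kernel, "response_kernel"),
            inherits(history, "concentration_history"))
  if (now < 1L || now > length(history$values))
    stop("'now' must index a recorded step")
  idx <- now - .lag_steps(kernel$lag, history$dt)
  val <- ifelse(idx >= 1L, history$values[pmax(idx, 1L)], history$fill)
  sum(kernel$weight * val)
}
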