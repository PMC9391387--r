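#' Configuration of the unidirectionally coupled Rossler benchmark
#'
#' Two three-dimensional Rossler oscillators; the master (subscript 1)
#' drives the slave (subscript 2) through a diffusive coupling
#' `epsilon * (x1 - x2)` entering only the `x2` equation.  Defaults are
#' the benchmark regime: `a = 0.15`, `b = 0.2`, `c = 10`, mismatched
#' frequencies `omega1 = 1.015`, `omega2 = 0.985`, coupling
#' `epsilon = 0.09`, sampling interval `0.314` (17-21 samples per
#' oscillation period) and 5000 discarded transient samples.
#'
#' @param a1,a2,b1,b2,c1,c2 Rossler parameters (dimensionless).
#' @param omega1,omega2 natural frequencies of master and slave.
#' @param epsilon coupling strength (`>= 0`); the master is autonomous.
#' @param dt_sample sampling interval in model time units.
#' @param n_transient initial samples discarded.
#' @param n_samples samples retained after the transient.
#' @param seed optional integer seed for the random initial condition
#'   (uniform in `x, y in [-5, 5]`, `z in [0, 1]` for each oscillator).
#'
#' @return A list of class `"rossler_config"`.
#' @export
rossler_config <- function(a1 = 0.15, a2 = 0.15, b1 = 0.2, b2 = 0.2,
                           c1 = 10, c2 = 10,
                           omega1 = 1.015, omega2 = 0.985,
                           epsilon = 0.09, dt_sample = 0.314,
                           n_transient = 5000, n_samples = 2048,
                           seed = NULL) {
  stopifnot(epsilon >= 0, dt_sample > 0, n_transient >= 0, n_samples >= 1)
  structure(list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 omega1 = omega1, omega2 = omega2, epsilon = epsilon,
                 dt_sample = dt_sample,
                 n_transient = as.integer(n_transient),
                 n_samples = as.integer(n_samples), seed = seed),
            class = "rossler_config")
}

rossler_deriv <- function(t, state, p) {
  x1 <- state[1L]; y1 <- state[2L]; z1 <- state[3L]
  x2 <- state[4L]; y2 <- state[5L]; z2 <- state[6L]
  list(c(-p$omega1 * y1 - z1,
         p$omega1 * x1 + p$a1 * y1,
         p$b1 + z1 * (x1 - p$c1),
         -p$omega2 * y2 - z2 + p$epsilon * (x1 - x2),
         p$omega2 * x2 + p$a2 * y2,
         p$b2 + z2 * (x2 - p$c2)))
}

#' Simulate the coupled Rossler benchmark
#'
#' Integrates the six-dimensional system with an adaptive high-accuracy
#' scheme (`deSolve::ode`, lsoda, relative and absolute tolerance 1e-9),
#' samples the state every `dt_sample`, discards the first `n_transient`
#' samples and returns `n_samples` points of both trajectories.
#'
#' @param config a [rossler_config()].
#' @return A data frame with columns `t`, `x1`, `y1`, `z1`, `x2`, `y2`,
#'   `z2`.
#' @examples
#' \donttest{
#' sim <- simulate_coupled_rossler(rossler_config(n_samples = 256, seed = 1))
#' }
#' @export
simulate_coupled_rossler <- function(config) {
  stopifnot(inherits(config, "rossler_config"))
  init <- with_seed(config$seed, {
    c(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0, 1),
      runif(1, -5, 5), runif(1, -5, 5), runif(1, 0, 1))
  })
  n_total <- config$n_transient + config$n_samples
  times <- (seq_len(n_total) - 1L) * config$dt_sample
  sol <- deSolve::ode(y = init, times = times, func = rossler_deriv,
                      parms = config, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9, maxsteps = 1e5)
  if (nrow(sol) < n_total || any(!is.finite(sol)))
    stop("integrator failure: non-finite state in Rossler simulation",
         call. = FALSE)
  keep <- (config$n_transient + 1L):n_total
  out <- as.data.frame(sol[keep, , drop = FALSE])
  names(out) <- c("t", "x1", "y1", "z1", "x2", "y2", "z2")
  rownames(out) <- NULL
  out
}

#' Inter-maximum sample counts of an oscillatory series
#'
#' Detects strict three-point local maxima and returns the numbers of
#' samples between successive maxima — the per-period sampling density
#' used to validate the benchmark sampling interval.
#'
#' @param x numeric vector.
#' @return Integer vector of inter-maximum sample counts.
#' @export
samples_per_period <- function(x) {
  x <- check_numeric_series(x, "x")
  n <- length(x)
  if (n < 3L) return(integer(0))
  peaks <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                 x[2:(n - 1L)] > x[3:n]) + 1L
  diff(peaks)
}

#' Add observational white noise scaled to the series
#'
#' Adds iid Gaussian noise with standard deviation
#' `(percent / 100) * sd(series)`, so `percent = 20` means the noise sd is
#' 20% of the signal sd and `percent = 100` matches it.
#'
#' @param series numeric vector.
#' @param percent noise level as a percentage of the signal sd (`>= 0`).
#' @param seed optional integer seed.
#' @return The noisy series (unchanged when `percent = 0`).
#' @export
add_noise <- function(series, percent, seed = NULL) {
  series <- check_numeric_series(series)
  stopifnot(percent >= 0)
  if (percent == 0) return(series)
  with_seed(seed,
            series + rnorm(length(series), 0, (percent / 100) * sd(series)))
}

#' Missing-sample (sparsity) specification
#'
#' A fraction `alpha` of samples is deleted at randomly chosen time
#' indices — one shared index set for both series (`"sync"`) or two
#' independent sets (`"async"`) — and the remainders are concatenated, so
#' downstream measures see shortened series with no gap markers.
#'
#' @param alpha fraction of deleted samples in `[0, 1)`.
#' @param mode `"sync"` or `"async"`.
#' @param seed optional integer seed for the index draw.
#' @return A list of class `"sparsity_spec"`.
#' @examples
#' sparsity_spec(0.2, "sync", seed = 1)
#' @export
sparsity_spec <- function(alpha, mode = c("sync", "async"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, alpha < 1)
  structure(list(alpha = alpha, mode = mode, seed = seed),
            class = "sparsity_spec")
}

# Draw the deletion index sets for series of length n.
deletion_indices <- function(n, spec, seed = NULL) {
  stopifnot(inherits(spec, "sparsity_spec"))
  m <- round(spec$alpha * n)
  if (m >= n) stop("cannot delete every sample", call. = FALSE)
  with_seed(seed %||% spec$seed, {
    idx_x <- sort(sample.int(n, m))
    idx_y <- if (spec$mode == "sync") idx_x else sort(sample.int(n, m))
    list(idx_x = idx_x, idx_y = idx_y)
  })
}

#' Delete samples from a pair of series
#'
#' Applies a [sparsity_spec()]: draws the deletion index sets, removes
#' those samples from each series and concatenates the remainder.
#'
#' @param x,y equal-length numeric series.
#' @param spec a [sparsity_spec()].
#' @return A list with shortened `x`, `y` and the deletion sets `idx_x`,
#'   `idx_y`.
#' @export
sparsify <- function(x, y, spec) {
  x <- check_numeric_series(x, "x")
  y <- check_numeric_series(y, "y")
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  del <- deletion_indices(length(x), spec)
  keep_x <- setdiff(seq_along(x), del$idx_x)
  keep_y <- setdiff(seq_along(y), del$idx_y)
  list(x = x[keep_x], y = y[keep_y],
       idx_x = del$idx_x, idx_y = del$idx_y)
}
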