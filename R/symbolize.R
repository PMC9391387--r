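#' Delay embedding of a scalar time series
#'
#' Builds the matrix of delay vectors used for phase-space reconstruction.
#' In `"forward"` mode the vector anchored at time `t` is
#' `(x(t), x(t + eta), ..., x(t + (m-1) eta))`; in `"backward"` mode it is
#' `(x(t), x(t - eta), ..., x(t - (m-1) eta))`.  The anchor index of the
#' first vector is kept in the `t0` attribute (0-based) so a partner series
#' can be co-truncated to the same time range.
#'
#' @param series numeric vector, length `N > (m-1) * eta`.
#' @param m embedding dimension (`m >= 1`).
#' @param eta embedding delay in samples (`eta >= 1`).
#' @param direction `"forward"` or `"backward"`.
#'
#' @return A numeric matrix of class `"embedded_series"` with
#'   `N - (m-1) * eta` rows and `m` columns, and attributes `m`, `eta`,
#'   `direction`, `t0`.
#' @examples
#' delay_embed(1:5, m = 3, eta = 1)
#' delay_embed(1:5, m = 3, eta = 2)
#' @export
delay_embed <- function(series, m, eta, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  series <- check_numeric_series(series)
  stopifnot(m >= 1, eta >= 1)
  m <- as.integer(m); eta <- as.integer(eta)
  n <- length(series)
  n_vec <- n - (m - 1L) * eta
  if (n_vec < 1L)
    stop(sprintf("insufficient length: need > %d samples for m=%d, eta=%d",
                 (m - 1L) * eta, m, eta), call. = FALSE)
  offsets <- (0L:(m - 1L)) * eta
  if (direction == "forward") {
    idx <- outer(seq_len(n_vec) - 1L, offsets, `+`) + 1L
    t0 <- 0L
  } else {
    idx <- outer(((m - 1L) * eta):(n - 1L), -offsets, `+`) + 1L
    t0 <- (m - 1L) * eta
  }
  v <- matrix(series[idx], nrow = n_vec, ncol = m)
  structure(v, m = m, eta = eta, direction = direction, t0 = t0,
            class = c("embedded_series", "matrix", "array"))
}

#' @export
print.embedded_series <- function(x, ...) {
  cat(sprintf("<embedded_series> %d vectors, m = %d, eta = %d, %s, t0 = %d\n",
              nrow(x), attr(x, "m"), attr(x, "eta"),
              attr(x, "direction"), attr(x, "t0")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more vectors\n", nrow(x) - 6L))
  invisible(x)
}

#' Ordinal (permutation) pattern encoding
#'
#' Converts each delay vector into a single symbol by ranking its values in
#' ascending order: label 0 goes to the lowest value and `m - 1` to the
#' highest.  Exact ties are broken by order of occurrence, the earlier
#' occurrence receiving the smaller label, so e.g. the vectors
#' `(3,5,5)`, `(3,3,5)` and `(3,3,3)` all map to the pattern `(0,1,2)`.
#' The rank pattern is then mapped to its lexicographic index among the
#' `m!` permutations, giving a symbol sequence on an alphabet of size `m!`.
#'
#' @param embedded an [delay_embed()] result (or plain numeric matrix).
#'
#' @return A [symbol_seq()] with `alphabet_size = factorial(m)`.
#' @examples
#' e <- delay_embed(c(3, 5, 5, 5, 5), m = 3, eta = 1)
#' ordinal_encode(e)
#' @export
ordinal_encode <- function(embedded) {
  v <- unclass(embedded)
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
  storage.mode(v) <- "double"
  n <- nrow(v); m <- ncol(v)
  if (n < 1L) stop("embedded series is empty", call. = FALSE)
  # rank of each coordinate within its vector, ties by occurrence order
  r <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (k == j) next
      r[, j] <- r[, j] + (v[, k] < v[, j] | (v[, k] == v[, j] & k < j))
    }
  }
  # Lehmer code: lexicographic index of the rank pattern among permutations
  idx <- integer(n)
  if (m > 1L) {
    fact <- rev(cumprod(c(1, seq_len(m - 1L))))  # (m-1)!, (m-2)!, ..., 1
    for (j in seq_len(m - 1L)) {
      cj <- integer(n)
      for (k in (j + 1L):m) cj <- cj + (r[, k] < r[, j])
      idx <- idx + cj * fact[j]
    }
  }
  symbol_seq(idx, alphabet_size = factorial(m))
}

#' Equidistant amplitude binning
#'
#' Partitions the range `[min(series), max(series)]` into `B` equal-width
#' bins; the maximum value is assigned to the last bin (right-closed top
#' bin).  A constant series maps to all zeros.  Bin edges are computed over
#' the full series, so windows cut later reuse the same global symbols.
#'
#' @param series numeric vector (finite values).
#' @param B number of bins (`B >= 1`).
#'
#' @return A [symbol_seq()] with `alphabet_size = B`.
#' @examples
#' equidistant_bin(c(0, 0.5, 1), B = 2)
#' @export
equidistant_bin <- function(series, B) {
  series <- check_numeric_series(series)
  stopifnot(B >= 1)
  B <- as.integer(B)
  lo <- min(series); hi <- max(series)
  if (lo == hi) return(symbol_seq(rep(0L, length(series)), alphabet_size = B))
  edges <- seq(lo, hi, length.out = B + 1L)
  sym <- findInterval(series, edges, rightmost.closed = TRUE,
                      all.inside = TRUE) - 1L
  symbol_seq(sym, alphabet_size = B)
}

#' Equiquantal (marginal-equiprobable) binning
#'
#' Bin edges at the empirical quantiles `k/Q`, so each symbol receives
#' `floor(N/Q)` or `ceiling(N/Q)` samples up to ties.  This is the
#' estimator used for continuous-valued conditional mutual information.
#'
#' @param series numeric vector with at least `Q` distinct values.
#' @param Q number of bins (`Q >= 2`).
#'
#' @return A [symbol_seq()] with `alphabet_size = Q`.
#' @examples
#' table(as.integer(equiquantal_bin(1:100, Q = 4)))
#' @export
equiquantal_bin <- function(series, Q) {
  series <- check_numeric_series(series)
  stopifnot(Q >= 2)
  Q <- as.integer(Q)
  if (length(unique(series)) < Q)
    stop(sprintf("need at least %d distinct values for %d equiquantal bins",
                 Q, Q), call. = FALSE)
  edges <- quantile(series, probs = seq_len(Q - 1L) / Q, names = FALSE, type = 7)
  sym <- findInterval(series, edges)
  symbol_seq(sym, alphabet_size = Q)
}

#' Embedding-delay selection by the first minimum of auto mutual information
#'
#' Computes the binned auto mutual information of the series at lags
#' `0 ... max_lag` and returns the smallest lag `k >= 1` that is a strict
#' local minimum of the curve.  If no local minimum exists within
#' `max_lag`, the lag of the global minimum is returned with attribute
#' `local_minimum = FALSE` and a warning.
#'
#' @param series numeric vector, much longer than `max_lag`.
#' @param max_lag largest lag considered (`max_lag >= 2`).
#' @param bins number of equiquantal bins for the MI estimate.
#'
#' @return Integer lag; attributes `auto_mi` (the MI curve, nats, lags
#'   `0:max_lag`) and `local_minimum` (logical).
#' @examples
#' x <- sin(2 * pi * (1:2000) / 20)
#' select_delay_auto_mi(x, max_lag = 15)
#' @export
select_delay_auto_mi <- function(series, max_lag, bins = 16) {
  series <- check_numeric_series(series)
  if (max_lag < 2) stop("`max_lag` must be >= 2 to bracket a minimum", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (length(series) <= 2L * max_lag)
    stop("series too short relative to `max_lag`", call. = FALSE)
  if (min(series) == max(series))
    stop("constant series has zero entropy; delay is undefined", call. = FALSE)
  sym <- as.integer(equiquantal_bin(series, bins))
  n <- length(sym)
  mi <- vapply(0:max_lag, function(k) {
    a <- sym[seq_len(n - k)]
    b <- sym[(k + 1L):n]
    joint_entropy(a) + joint_entropy(b) - joint_entropy(a, b)
  }, numeric(1))
  interior <- which(mi[2:max_lag] < mi[1:(max_lag - 1L)] &
                    mi[2:max_lag] < mi[3:(max_lag + 1L)])
  if (length(interior) > 0L) {
    lag <- interior[1L]
    local_min <- TRUE
  } else {
    lag <- which.min(mi[-1L])
    local_min <- FALSE
    warning("no local minimum of auto-MI within `max_lag`; returning global minimum",
            call. = FALSE)
  }
  structure(as.integer(lag), auto_mi = mi, local_minimum = local_min)
}
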