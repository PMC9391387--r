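#' Window geometry for compression-complexity causality
#'
#' @param L past-window length in samples (`L >= 2`).
#' @param w future-window length in samples (`w >= 1`).
#' @param delta window step in samples (`delta >= 1`).
#' @param B number of amplitude bins used to symbolize raw series
#'   (`B >= 2`).  For the permutation variant [pccc()] `B` is forced to
#'   `factorial(m)`.
#' @param normalized if `TRUE`, compression-complexity terms use ETC
#'   normalized by sequence length instead of raw substitution counts.
#'
#' @return A list of class `"ccc_params"`.
#' @examples
#' ccc_params(L = 25, w = 15, delta = 20)         # permutation-CCC geometry
#' ccc_params(L = 300, w = 30, delta = 30, B = 8) # scalar-CCC geometry
#' @export
ccc_params <- function(L, w, delta, B = 8, normalized = FALSE) {
  stopifnot(L >= 2, w >= 1, delta >= 1, B >= 2)
  structure(list(L = as.integer(L), w = as.integer(w),
                 delta = as.integer(delta), B = as.integer(B),
                 normalized = isTRUE(normalized)),
            class = "ccc_params")
}

# ETC value under the configured scaling (raw step count by default).
etc_value <- function(steps, len, normalized) {
  if (!normalized) return(as.numeric(steps))
  if (len > 1L) steps / (len - 1) else 0
}

#' Compression-complexity of a future window given its own past
#'
#' `CC(dy | y_past) = ETC(y_past + dy) - ETC(y_past)`: the additional
#' compression effort induced by the future window `dy` when appended to
#' the past window of the same series.
#'
#' @param y_past past window, a [symbol_seq()] of length `L`.
#' @param dy future window, a [symbol_seq()] of length `w` on the same
#'   alphabet.
#' @param normalized use length-normalized ETC values.
#' @return A real number (may be negative).
#' @examples
#' window_cc_self(symbol_seq(c(0, 1, 0, 1)), symbol_seq(c(1, 1)))
#' @export
window_cc_self <- function(y_past, dy, normalized = FALSE) {
  y_past <- as_symbol_seq(y_past); dy <- as_symbol_seq(dy)
  yy <- concat_symbols(y_past, dy)
  etc_value(cpp_etc_steps(as.integer(yy), alphabet_size(yy)),
            length(yy), normalized) -
    etc_value(cpp_etc_steps(as.integer(y_past), alphabet_size(y_past)),
              length(y_past), normalized)
}

#' Compression-complexity of a future window given both pasts
#'
#' `CC(dy | y_past, x_past) = ETC(y_past + dy, x_past + dy) -
#' ETC(y_past, x_past)`, where the two-argument ETC compresses the
#' product-alphabet pair sequence ([joint_etc()]).
#'
#' @param y_past,x_past past windows of length `L`.
#' @param dy future window of length `w`.
#' @param normalized use length-normalized ETC values.
#' @return A real number (may be negative).
#' @export
window_cc_joint <- function(y_past, x_past, dy, normalized = FALSE) {
  y_past <- as_symbol_seq(y_past); x_past <- as_symbol_seq(x_past)
  dy <- as_symbol_seq(dy)
  if (length(y_past) != length(x_past))
    stop("`y_past` and `x_past` must have equal length", call. = FALSE)
  yy <- c(as.integer(y_past), as.integer(dy))
  xx <- c(as.integer(x_past), as.integer(dy))
  etc_value(cpp_joint_etc_steps(yy, xx), length(yy), normalized) -
    etc_value(cpp_joint_etc_steps(as.integer(y_past), as.integer(x_past)),
              length(y_past), normalized)
}

#' Compression-complexity causality between symbol sequences
#'
#' Windowed CCC from `x` to `y`: past windows `y_past`, `x_past` of length
#' `L` and the following future window `dy` of length `w` are slid along
#' the series in steps of `delta`; for each window the self term
#' `CC(dy | y_past)` and the joint term `CC(dy | y_past, x_past)` are
#' accumulated, and their difference of means is the averaged CCC.  A value
#' near zero means `x` adds nothing to the compressibility of `y`'s
#' dynamics; the sign carries the nature of the coupling, the magnitude its
#' strength.  Callers symbolize raw data first (see [equidistant_bin()],
#' [pccc()]).
#'
#' @param x,y equal-length [symbol_seq()] objects (already symbolized).
#' @param params a [ccc_params()] window geometry.
#'
#' @return A list of class `"ccc_result"` with `ccc`,
#'   `per_window_cc_self`, `per_window_cc_joint` and `n_windows`.
#' @examples
#' s <- equidistant_bin(sin(1:300), B = 4)
#' ccc(s, s, ccc_params(L = 25, w = 15, delta = 20))$ccc  # identical: 0
#' @export
ccc <- function(x, y, params) {
  stopifnot(inherits(params, "ccc_params"))
  x <- as_symbol_seq(x); y <- as_symbol_seq(y)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  L <- params$L; w <- params$w; delta <- params$delta
  if (n < L + w)
    stop(sprintf("series too short for window geometry: need >= %d samples, have %d",
                 L + w, n), call. = FALSE)
  norm <- params$normalized
  xi <- as.integer(x); yi <- as.integer(y)
  starts <- seq.int(0L, n - L - w, by = delta)
  cc_self <- numeric(length(starts))
  cc_joint <- numeric(length(starts))
  ay <- alphabet_size(y)
  for (k in seq_along(starts)) {
    s <- starts[k]
    yp <- yi[(s + 1L):(s + L)]
    xp <- xi[(s + 1L):(s + L)]
    dy <- yi[(s + L + 1L):(s + L + w)]
    ypdy <- c(yp, dy)
    cc_self[k] <- etc_value(cpp_etc_steps(ypdy, ay), L + w, norm) -
      etc_value(cpp_etc_steps(yp, ay), L, norm)
    cc_joint[k] <- etc_value(cpp_joint_etc_steps(ypdy, c(xp, dy)), L + w, norm) -
      etc_value(cpp_joint_etc_steps(yp, xp), L, norm)
  }
  structure(list(ccc = mean(cc_self) - mean(cc_joint),
                 per_window_cc_self = cc_self,
                 per_window_cc_joint = cc_joint,
                 n_windows = length(starts),
                 params = params),
            class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("<ccc_result> CCC = %.6g over %d windows (L=%d, w=%d, delta=%d)\n",
              x$ccc, x$n_windows, x$params$L, x$params$w, x$params$delta))
  invisible(x)
}

#' Permutation compression-complexity causality (PCCC)
#'
#' CCC from a delay-embedded, ordinal-encoded driver to an
#' equidistantly binned target.  The potential driver `x_raw` is
#' forward-embedded with dimension `m` and delay `eta_x` and each delay
#' vector replaced by its ordinal pattern (alphabet `m!`); the target
#' `y_raw` is truncated to the same time range and binned into `m!`
#' equal-width amplitude bins.  Only the cause is embedded: full
#' dimensionality of the cause suffices to predict the effect, and leaving
#' the effect as a scalar series preserves the interventional window
#' structure of CCC.  For the reverse direction call
#' `pccc(y_raw, x_raw, m, eta_y, params)`.
#'
#' @param x_raw potential driver, numeric vector.
#' @param y_raw potential response, numeric vector of the same length.
#' @param m embedding dimension (alphabets become `m!`).
#' @param eta_x embedding delay of the driver, in samples.
#' @param params a [ccc_params()]; its `B` is overridden by `m!`.
#'
#' @return A `"ccc_result"` (see [ccc()]) with embedding metadata attached.
#' @examples
#' x <- cumsum(rnorm(400)); y <- cumsum(rnorm(400))
#' pccc(x, y, m = 3, eta_x = 5, ccc_params(L = 25, w = 15, delta = 20))
#' @export
pccc <- function(x_raw, y_raw, m, eta_x, params) {
  stopifnot(inherits(params, "ccc_params"))
  x_raw <- check_numeric_series(x_raw, "x_raw")
  y_raw <- check_numeric_series(y_raw, "y_raw")
  if (length(x_raw) != length(y_raw))
    stop("`x_raw` and `y_raw` must have equal length", call. = FALSE)
  xs <- ordinal_encode(delay_embed(x_raw, m = m, eta = eta_x,
                                   direction = "forward"))
  n_s <- length(xs)
  B <- factorial(as.integer(m))
  ys <- equidistant_bin(y_raw[seq_len(n_s)], B = B)
  p <- params
  p$B <- as.integer(B)
  res <- ccc(xs, ys, p)
  res$m <- as.integer(m)
  res$eta_x <- as.integer(eta_x)
  res
}
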