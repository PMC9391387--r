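# Plug-in information-theoretic coupling measures.  Probabilities are raw
# empirical counts / n (no pseudocounts); bias is handled by surrogate
# calibration downstream, not analytic correction.  Natural logs (nats).

# Collapse equal-length symbol columns to one integer key per row.
tuple_key <- function(cols) {
  key <- rep(0, length(cols[[1L]]))
  base <- 1
  for (col in cols) {
    key <- key + base * as.numeric(unclass(col))
    base <- base * max(alphabet_size(col), max(as.integer(col)) + 1L)
  }
  key
}

entropy_from_key <- function(key) {
  p <- tabulate(match(key, unique(key)))
  p <- p / length(key)
  -sum(p * log(p))
}

#' Joint Shannon entropy of symbol columns (nats)
#'
#' Plug-in entropy `H(X1, X2, ...) = -sum p log p` of the empirical joint
#' distribution of the column tuples, with `0 log 0 = 0` and natural
#' logarithms.
#'
#' @param ... one or more equal-length [symbol_seq()] objects (or integer
#'   vectors), each a column of the joint distribution.
#' @return Entropy in nats (non-negative).
#' @examples
#' joint_entropy(symbol_seq(c(0, 0, 1, 1)))               # log(2)
#' joint_entropy(symbol_seq(c(0, 1, 0, 1)), symbol_seq(c(0, 0, 1, 1)))
#' @export
joint_entropy <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1L]]) && !inherits(cols[[1L]], "symbol_seq"))
    cols <- cols[[1L]]
  if (length(cols) < 1L || length(cols[[1L]]) < 1L)
    stop("joint entropy needs at least one non-empty column", call. = FALSE)
  n <- length(cols[[1L]])
  if (!all(vapply(cols, length, integer(1)) == n))
    stop("all columns must have equal length", call. = FALSE)
  entropy_from_key(tuple_key(cols))
}

#' Conditional mutual information of symbol sequences (nats)
#'
#' `I(X; Y | Z) = H(X, Z) + H(Y, Z) - H(X, Y, Z) - H(Z)` from plug-in
#' joint entropies.  With an empty conditioning set this reduces to the
#' mutual information `I(X; Y)`.
#'
#' @param x,y equal-length [symbol_seq()] objects.
#' @param z conditioning set: a [symbol_seq()], a list of them, or `NULL`.
#' @return CMI in nats (non-negative up to rounding).
#' @examples
#' x <- symbol_seq(c(0, 1, 0, 1)); z <- symbol_seq(rep(0, 4))
#' cmi(x, x, z)   # = H(X) = log(2)
#' @export
cmi <- function(x, y, z = NULL) {
  if (!is.null(z) && !is.list(z)) z <- list(z)
  n <- length(x)
  if (length(y) != n || (!is.null(z) && !all(vapply(z, length, integer(1)) == n)))
    stop("`x`, `y` and all conditioning columns must have equal length",
         call. = FALSE)
  if (is.null(z) || length(z) == 0L)
    return(joint_entropy(x) + joint_entropy(y) - joint_entropy(list(x, y)))
  joint_entropy(c(list(x), z)) + joint_entropy(c(list(y), z)) -
    joint_entropy(c(list(x, y), z)) - joint_entropy(z)
}

#' Parameters for conditional mutual information measures
#'
#' @param tau prediction horizon in samples (`tau >= 1`).  May be a vector
#'   of horizons, in which case the measures report the mean over the
#'   range (the aggregation used for irregularly sampled records probed at
#'   `tau = 1 ... 30`).
#' @param m embedding dimension for the condition/permutation variants.
#' @param eta embedding delay in samples.
#' @param Q number of equiquantal bins for continuous-valued series.
#'
#' @return A list of class `"cmi_params"`.
#' @examples
#' cmi_params(tau = 20, m = 3, eta = 5)
#' @export
cmi_params <- function(tau = 1, m = 3, eta = 1, Q = 8) {
  stopifnot(all(tau >= 1), m >= 1, eta >= 1, Q >= 2)
  structure(list(tau = as.integer(tau), m = as.integer(m),
                 eta = as.integer(eta), Q = as.integer(Q)),
            class = "cmi_params")
}

# Mean over the tau grid of a single-horizon evaluator.
mean_over_tau <- function(taus, f) mean(vapply(taus, f, numeric(1)))

#' Scalar conditional mutual information CMI1
#'
#' `I(x(t); y(t + tau) | y(t))`: the net information the driver candidate
#' `x` carries about the `tau`-step future of `y` beyond `y`'s own
#' present.  Both series are equiquantally binned with `Q` bins before the
#' plug-in estimate.
#'
#' @param x_raw,y_raw equal-length numeric series.
#' @param params a [cmi_params()]; uses `tau` and `Q`.
#' @return CMI in nats (mean over `params$tau` if a vector).
#' @export
cmi1 <- function(x_raw, y_raw, params) {
  stopifnot(inherits(params, "cmi_params"))
  x_raw <- check_numeric_series(x_raw, "x_raw")
  y_raw <- check_numeric_series(y_raw, "y_raw")
  n <- length(x_raw)
  if (length(y_raw) != n) stop("series must have equal length", call. = FALSE)
  if (n <= max(params$tau) + 1L)
    stop("series too short for prediction horizon `tau`", call. = FALSE)
  xs <- as.integer(equiquantal_bin(x_raw, params$Q))
  ys <- as.integer(equiquantal_bin(y_raw, params$Q))
  mean_over_tau(params$tau, function(tau) {
    t <- seq_len(n - tau)
    cmi(xs[t], ys[t + tau], list(ys[t]))
  })
}

#' Condition-embedded conditional mutual information CMI3
#'
#' `I(x(t); y(t + tau) | y(t), y(t - eta), ..., y(t - (m-1) eta))`:
#' as [cmi1()] but conditioning on the `m` backward-embedded coordinates
#' of the response, which suffices to infer the direction of coupling
#' between multidimensional dynamical systems.  `m = 1` reduces exactly to
#' [cmi1()].
#'
#' @inheritParams cmi1
#' @param params a [cmi_params()]; uses `tau`, `m`, `eta`, `Q`.
#' @return CMI in nats (mean over `params$tau` if a vector).
#' @export
cmi3 <- function(x_raw, y_raw, params) {
  stopifnot(inherits(params, "cmi_params"))
  x_raw <- check_numeric_series(x_raw, "x_raw")
  y_raw <- check_numeric_series(y_raw, "y_raw")
  n <- length(x_raw)
  if (length(y_raw) != n) stop("series must have equal length", call. = FALSE)
  m <- params$m; eta <- params$eta
  if (n <= max(params$tau) + (m - 1L) * eta)
    stop("series too short for `tau` and the backward embedding", call. = FALSE)
  xs <- as.integer(equiquantal_bin(x_raw, params$Q))
  ys <- as.integer(equiquantal_bin(y_raw, params$Q))
  mean_over_tau(params$tau, function(tau) {
    t <- ((m - 1L) * eta + 1L):(n - tau)
    cond <- lapply(0L:(m - 1L), function(j) ys[t - j * eta])
    cmi(xs[t], ys[t + tau], cond)
  })
}

#' Permutation conditional mutual information PCMI
#'
#' Both series are forward-embedded with `(m, eta)` and ordinal-encoded
#' (alphabet `m!`), and the scalar CMI is evaluated on the symbol
#' sequences with the horizon shifted to `tau' = tau + (m - 1) eta` so the
#' symbolized past and future of the response do not overlap:
#' `I(x-hat(t); y-hat(t + tau') | y-hat(t))`.  Equivalent to symbolic
#' transfer entropy.
#'
#' @inheritParams cmi1
#' @param params a [cmi_params()]; uses `tau`, `m`, `eta`.
#' @return CMI in nats (mean over `params$tau` if a vector).
#' @export
pcmi <- function(x_raw, y_raw, params) {
  stopifnot(inherits(params, "cmi_params"))
  x_raw <- check_numeric_series(x_raw, "x_raw")
  y_raw <- check_numeric_series(y_raw, "y_raw")
  n <- length(x_raw)
  if (length(y_raw) != n) stop("series must have equal length", call. = FALSE)
  m <- params$m; eta <- params$eta
  if (n <= max(params$tau) + 2L * (m - 1L) * eta)
    stop("series too short for `tau` plus the forward embedding", call. = FALSE)
  xs <- as.integer(ordinal_encode(delay_embed(x_raw, m, eta, "forward")))
  ys <- as.integer(ordinal_encode(delay_embed(y_raw, m, eta, "forward")))
  n_s <- length(xs)
  mean_over_tau(params$tau, function(tau) {
    tau2 <- tau + (m - 1L) * eta
    t <- seq_len(n_s - tau2)
    cmi(xs[t], ys[t + tau2], list(ys[t]))
  })
}
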