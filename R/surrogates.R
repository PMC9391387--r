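#' Amplitude-adjusted Fourier transform (AAFT) surrogate
#'
#' Classic single-iteration AAFT: (1) a Gaussian white series is reordered
#' to match the ranks of the data; (2) its Fourier phases are randomized
#' under conjugate symmetry, preserving the amplitude spectrum; (3) the
#' original values are reordered to match the ranks of the
#' phase-randomized series.  The surrogate is therefore an exact
#' permutation of the original values that approximately preserves the
#' power spectrum while destroying nonlinear (and cross-) dependence.
#'
#' @param series numeric vector of length >= 8 with finite values.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return A numeric vector: a permutation of `series`.
#' @examples
#' x <- as.numeric(arima.sim(list(ar = 0.8), 128))
#' s <- aaft_surrogate(x, seed = 1)
#' identical(sort(s), sort(x))
#' @export
aaft_surrogate <- function(series, seed = NULL) {
  series <- check_numeric_series(series)
  n <- length(series)
  if (n < 8L) stop("AAFT needs at least 8 samples", call. = FALSE)
  if (min(series) == max(series)) return(series)
  with_seed(seed, {
    g <- sort(rnorm(n))[rank(series, ties.method = "first")]
    gp <- phase_randomize(g)
    sort(series)[rank(gp, ties.method = "first")]
  })
}

# Randomize Fourier phases with conjugate symmetry; DC (and Nyquist for
# even n) components are kept real.
phase_randomize <- function(x) {
  n <- length(x)
  f <- fft(x)
  rot <- rep(1 + 0i, n)
  half <- if (n %% 2L == 0L) n / 2L - 1L else (n - 1L) / 2L
  if (half >= 1L) {
    phi <- runif(half, 0, 2 * pi)
    rot[2L:(half + 1L)] <- exp(1i * phi)
    rot[n:(n - half + 1L)] <- Conj(rot[2L:(half + 1L)])
  }
  Re(fft(f * rot, inverse = TRUE)) / n
}

#' Stationary bootstrap surrogate
#'
#' Concatenates blocks of geometrically distributed random length (mean
#' `1/p_geom`) starting at uniform random positions, with circular
#' wrap-around, until the original length is reached; the overshoot is
#' truncated.  Used as the surrogate generator for irregularly sampled
#' real-world records (conventional block-length parameter `p_geom = 0.1`).
#'
#' @param series numeric vector.
#' @param p_geom success probability of the geometric block-length law,
#'   in (0, 1).
#' @param seed optional integer seed.
#' @return A numeric vector of the same length, drawing only observed
#'   values.
#' @export
stationary_bootstrap <- function(series, p_geom = 0.1, seed = NULL) {
  series <- check_numeric_series(series)
  if (!(p_geom > 0 && p_geom < 1))
    stop("`p_geom` must lie strictly between 0 and 1", call. = FALSE)
  n <- length(series)
  with_seed(seed, {
    idx <- integer(0)
    while (length(idx) < n) {
      start <- sample.int(n, 1L)
      len <- rgeom(1L, p_geom) + 1L
      idx <- c(idx, (start - 1L + seq_len(len) - 1L) %% n + 1L)
    }
    series[idx[seq_len(n)]]
  })
}

#' One-sided z-test of an original statistic against surrogates
#'
#' `z = (original - mean(surrogates)) / sd(surrogates)`; the statistic is
#' significant when `z` exceeds the one-sided normal quantile at
#' `alpha` (1.6449 for `alpha = 0.05`).  A degenerate surrogate
#' distribution (zero variance) yields a flagged, non-significant result.
#'
#' @param original the statistic computed on the original series.
#' @param surrogates numeric vector (>= 2) of the statistic on surrogates.
#' @param alpha one-sided significance level.
#' @return A list of class `"significance_result"` with `original_value`,
#'   `surrogate_values`, `z_score`, `p_threshold`, `significant` and
#'   `degenerate`.
#' @examples
#' significance_test(3, rnorm(100), alpha = 0.05)
#' @export
significance_test <- function(original, surrogates, alpha = 0.05) {
  stopifnot(is.numeric(original), length(original) == 1L,
            is.numeric(surrogates), length(surrogates) >= 2L,
            alpha > 0, alpha < 1)
  s <- sd(surrogates)
  if (!is.finite(s) || s == 0) {
    warning("degenerate surrogate distribution (zero variance)", call. = FALSE)
    return(structure(list(original_value = original,
                          surrogate_values = surrogates,
                          z_score = NA_real_, p_threshold = alpha,
                          significant = FALSE, degenerate = TRUE),
                     class = "significance_result"))
  }
  z <- (original - mean(surrogates)) / s
  structure(list(original_value = original, surrogate_values = surrogates,
                 z_score = z, p_threshold = alpha,
                 significant = z > qnorm(1 - alpha), degenerate = FALSE),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "<significance_result> original = %.6g, %d surrogates, z = %.3f, %s at one-sided p = %g%s\n",
    x$original_value, length(x$surrogate_values), x$z_score,
    if (isTRUE(x$significant)) "SIGNIFICANT" else "not significant",
    x$p_threshold,
    if (isTRUE(x$degenerate)) " (degenerate surrogate distribution)" else ""))
  invisible(x)
}

# Evaluate one directed measure value; `a` is the driver candidate.
measure_value <- function(measure, a, b, eta_a, m,
                          ccc_params = NULL, cmi_params = NULL) {
  switch(measure,
    ccc = {
      stopifnot(inherits(ccc_params, "ccc_params"))
      ccc(equidistant_bin(a, ccc_params$B),
          equidistant_bin(b, ccc_params$B), ccc_params)$ccc
    },
    pccc = pccc(a, b, m = m, eta_x = eta_a, params = ccc_params)$ccc,
    cmi1 = cmi1(a, b, cmi_params),
    cmi3 = cmi3(a, b, cmi_params),
    pcmi = pcmi(a, b, cmi_params),
    stop(sprintf("unknown measure '%s'", measure), call. = FALSE))
}

#' Surrogate-calibrated causality test, both directions
#'
#' Runs the full significance protocol for one pair of raw series:
#' `n_surr` surrogate pairs (surrogate i of `x` paired with surrogate i of
#' `y`) are generated from the full-length series; if a sparsity
#' specification is supplied, sample deletion is applied *after* surrogate
#' generation, with the same deletion index sets used for the originals
#' and every surrogate (the sampling structure of the tested pair is thus
#' shared by its null ensemble); the chosen measure is evaluated on the
#' original and all surrogate pairs in both directions; and each direction
#' is assessed with a one-sided z-test.
#'
#' @param x,y equal-length numeric series (`x -> y` is the first tested
#'   direction).
#' @param measure one of `"ccc"`, `"pccc"`, `"cmi1"`, `"cmi3"`, `"pcmi"`.
#' @param n_surr number of surrogate pairs (the simulation protocol uses
#'   100).
#' @param surrogate_method `"aaft"` (simulation protocol) or
#'   `"stationary_bootstrap"` (irregularly sampled records).
#' @param sparsity optional [sparsity_spec()] applied after surrogate
#'   generation.
#' @param seed optional integer master seed for surrogates and deletion.
#' @param ccc_params [ccc_params()] for `"ccc"`/`"pccc"`.
#' @param cmi_params [cmi_params()] for `"cmi1"`/`"cmi3"`/`"pcmi"`.
#' @param m embedding dimension for `"pccc"`.
#' @param eta_x,eta_y embedding delays of `x` and `y` for `"pccc"`.
#' @param alpha one-sided significance level.
#' @param p_geom block parameter for the stationary bootstrap.
#'
#' @return A list of class `"causality_test"` with elements `x_to_y` and
#'   `y_to_x` (each a [significance_test()] result) plus the protocol
#'   metadata.
#'
#' @details
#' For the compression-complexity measures (`"ccc"`, `"pccc"`) the sign of
#' the statistic encodes the nature of the coupling while its magnitude
#' encodes the strength, so the one-sided z-test is applied to the
#' coupling strength `|CCC|` of the original and of every surrogate pair;
#' the signed values are kept in the `signed_original` field.  The CMI
#' family is non-negative and is tested as is.
#' @export
causality_significance <- function(x, y,
                                   measure = c("ccc", "pccc", "cmi1", "cmi3", "pcmi"),
                                   n_surr = 100,
                                   surrogate_method = c("aaft", "stationary_bootstrap"),
                                   sparsity = NULL, seed = NULL,
                                   ccc_params = NULL, cmi_params = NULL,
                                   m = 3, eta_x = 1, eta_y = eta_x,
                                   alpha = 0.05, p_geom = 0.1) {
  measure <- match.arg(measure)
  surrogate_method <- match.arg(surrogate_method)
  x <- check_numeric_series(x, "x")
  y <- check_numeric_series(y, "y")
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  stopifnot(n_surr >= 2)
  n_surr <- as.integer(n_surr)
  n <- length(x)

  seeds <- seed_stream(seed, 2L * n_surr + 1L)
  gen <- switch(surrogate_method,
                aaft = aaft_surrogate,
                stationary_bootstrap = function(s, seed)
                  stationary_bootstrap(s, p_geom = p_geom, seed = seed))
  sx <- lapply(seq_len(n_surr), function(i) gen(x, seed = seeds[[i]]))
  sy <- lapply(seq_len(n_surr), function(i) gen(y, seed = seeds[[n_surr + i]]))

  if (!is.null(sparsity)) {
    del <- deletion_indices(n, sparsity, seed = seeds[[2L * n_surr + 1L]])
    keep_x <- setdiff(seq_len(n), del$idx_x)
    keep_y <- setdiff(seq_len(n), del$idx_y)
    x <- x[keep_x]; y <- y[keep_y]
    sx <- lapply(sx, `[`, keep_x)
    sy <- lapply(sy, `[`, keep_y)
  }

  eval_dir <- function(a, b, eta_a)
    measure_value(measure, a, b, eta_a = eta_a, m = m,
                  ccc_params = ccc_params, cmi_params = cmi_params)

  orig_xy <- eval_dir(x, y, eta_x)
  orig_yx <- eval_dir(y, x, eta_y)
  surr_xy <- vapply(seq_len(n_surr),
                    function(i) eval_dir(sx[[i]], sy[[i]], eta_x), numeric(1))
  surr_yx <- vapply(seq_len(n_surr),
                    function(i) eval_dir(sy[[i]], sx[[i]], eta_y), numeric(1))

  # CCC-family statistics are signed; significance is assessed on the
  # coupling strength (the magnitude), see Details.
  strength <- if (measure %in% c("ccc", "pccc")) abs else identity
  res_xy <- significance_test(strength(orig_xy), strength(surr_xy), alpha)
  res_yx <- significance_test(strength(orig_yx), strength(surr_yx), alpha)
  res_xy$signed_original <- orig_xy
  res_yx$signed_original <- orig_yx

  structure(list(x_to_y = res_xy,
                 y_to_x = res_yx,
                 measure = measure, n_surr = n_surr,
                 surrogate_method = surrogate_method,
                 sparsity = sparsity, alpha = alpha),
            class = "causality_test")
}

#' @export
print.causality_test <- function(x, ...) {
  cat(sprintf("<causality_test> measure = %s, %d %s surrogate pairs, alpha = %g\n",
              x$measure, x$n_surr, x$surrogate_method, x$alpha))
  cat("  x -> y: "); print(x$x_to_y)
  cat("  y -> x: "); print(x$y_to_x)
  invisible(x)
}
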