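#' Benchmark configuration for TPR/FPR sweeps
#'
#' Describes an ensemble experiment on the coupled Rossler benchmark: for
#' every condition in the (length / noise / sparsity) grid and every
#' realization, a fresh pair is simulated, optionally perturbed, and the
#' chosen measure is surrogate-tested in both directions.  The true
#' positive rate is the fraction of realizations with a significant
#' `x1 -> x2` call, the false positive rate the fraction with a
#' significant `x2 -> x1` call.
#'
#' @param measure one of `"ccc"`, `"pccc"`, `"cmi1"`, `"cmi3"`, `"pcmi"`.
#' @param n_realizations realizations per condition.
#' @param n_surrogates surrogate pairs per realization (`>= 2`).
#' @param lengths optional vector of series lengths `N`.
#' @param noise_percents optional vector of noise levels (percent of the
#'   signal sd).
#' @param sparsity_alphas optional vector of missing-sample fractions.
#' @param sparsity_mode `"sync"` or `"async"` (used with
#'   `sparsity_alphas`).
#' @param ccc_params a [ccc_params()] (for `"ccc"`/`"pccc"`).
#' @param cmi_params a [cmi_params()] (for the CMI family).
#' @param m embedding dimension for `"pccc"`.
#' @param eta_x,eta_y embedding delays of the two series.
#' @param alpha one-sided significance level.
#' @param surrogate_method `"aaft"` or `"stationary_bootstrap"`.
#' @param rossler a [rossler_config()] template (its `n_samples` and
#'   `seed` are overridden per condition/realization).
#' @param seed master seed; realization and surrogate seeds are spawned
#'   from it so any subset of the sweep is reproducible in isolation.
#'
#' @return A list of class `"bench_config"`.
#' @export
bench_config <- function(measure = "pccc",
                         n_realizations = 25, n_surrogates = 100,
                         lengths = NULL, noise_percents = NULL,
                         sparsity_alphas = NULL,
                         sparsity_mode = c("sync", "async"),
                         ccc_params = NULL, cmi_params = NULL,
                         m = 3, eta_x = 5, eta_y = 5,
                         alpha = 0.05,
                         surrogate_method = "aaft",
                         rossler = rossler_config(),
                         seed = 1) {
  sparsity_mode <- match.arg(sparsity_mode)
  stopifnot(n_realizations >= 1, n_surrogates >= 2)
  structure(list(measure = measure,
                 n_realizations = as.integer(n_realizations),
                 n_surrogates = as.integer(n_surrogates),
                 lengths = lengths, noise_percents = noise_percents,
                 sparsity_alphas = sparsity_alphas,
                 sparsity_mode = sparsity_mode,
                 ccc_params = ccc_params, cmi_params = cmi_params,
                 m = as.integer(m), eta_x = as.integer(eta_x),
                 eta_y = as.integer(eta_y),
                 alpha = alpha, surrogate_method = surrogate_method,
                 rossler = rossler, seed = seed),
            class = "bench_config")
}

bench_conditions <- function(config) {
  grid <- expand.grid(
    length = config$lengths %||% config$rossler$n_samples,
    noise_percent = config$noise_percents %||% 0,
    sparsity_alpha = config$sparsity_alphas %||% 0,
    stringsAsFactors = FALSE)
  grid$sparsity_mode <- ifelse(grid$sparsity_alpha > 0,
                               config$sparsity_mode, "none")
  grid
}

#' Run a TPR/FPR benchmark sweep
#'
#' Executes the ensemble experiment described by a [bench_config()]:
#' simulates each realization, applies the condition's perturbation,
#' runs [causality_significance()] in both directions, and tallies
#' true/false positive rates per condition.  A failing realization is
#' recorded with its condition metadata, never silently dropped.
#'
#' @param config a [bench_config()].
#' @param out_dir optional directory; if given, `results.csv`,
#'   `decisions.csv` and a machine-readable `manifest.json` are written
#'   there.
#' @param verbose print per-condition progress lines.
#'
#' @return A list of class `"bench_result"`: `results` (one row per
#'   condition with `tpr`, `fpr`, `n_ok`, `n_failed`), `decisions` (one
#'   row per realization with the per-direction calls and seeds) and the
#'   `config`.
#' @export
run_benchmark <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "bench_config"))
  conds <- bench_conditions(config)
  n_real <- config$n_realizations
  # one independent seed pair (simulation, protocol) per realization slot
  seeds <- seed_stream(config$seed, 2L * nrow(conds) * n_real)
  decisions <- vector("list", nrow(conds) * n_real)
  results <- conds
  results$tpr <- NA_real_; results$fpr <- NA_real_
  results$n_ok <- 0L; results$n_failed <- 0L

  row <- 0L
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, ]
    tp <- 0L; fp <- 0L; ok <- 0L; failed <- 0L
    for (ri in seq_len(n_real)) {
      row <- row + 1L
      sim_seed <- seeds[[2L * row - 1L]]
      proto_seed <- seeds[[2L * row]]
      rec <- list(condition = ci, realization = ri,
                  length = cond$length, noise_percent = cond$noise_percent,
                  sparsity_alpha = cond$sparsity_alpha,
                  sparsity_mode = cond$sparsity_mode,
                  sim_seed = sim_seed %||% NA_integer_,
                  proto_seed = proto_seed %||% NA_integer_,
                  x1_to_x2 = NA, x2_to_x1 = NA, error = NA_character_)
      res <- tryCatch({
        rc <- config$rossler
        rc$n_samples <- as.integer(cond$length)
        rc$seed <- sim_seed
        sim <- simulate_coupled_rossler(rc)
        x1 <- sim$x1; x2 <- sim$x2
        if (cond$noise_percent > 0) {
          ns <- seed_stream(proto_seed, 2L)
          x1 <- add_noise(x1, cond$noise_percent, seed = ns[[1L]])
          x2 <- add_noise(x2, cond$noise_percent, seed = ns[[2L]])
        }
        sp <- if (cond$sparsity_alpha > 0)
          sparsity_spec(cond$sparsity_alpha, cond$sparsity_mode) else NULL
        causality_significance(
          x1, x2, measure = config$measure,
          n_surr = config$n_surrogates,
          surrogate_method = config$surrogate_method,
          sparsity = sp, seed = proto_seed,
          ccc_params = config$ccc_params, cmi_params = config$cmi_params,
          m = config$m, eta_x = config$eta_x, eta_y = config$eta_y,
          alpha = config$alpha)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- failed + 1L
        rec$error <- conditionMessage(res)
      } else {
        ok <- ok + 1L
        rec$x1_to_x2 <- res$x_to_y$significant
        rec$x2_to_x1 <- res$y_to_x$significant
        tp <- tp + as.integer(res$x_to_y$significant)
        fp <- fp + as.integer(res$y_to_x$significant)
      }
      decisions[[row]] <- rec
    }
    results$tpr[ci] <- tp / n_real
    results$fpr[ci] <- fp / n_real
    results$n_ok[ci] <- ok
    results$n_failed[ci] <- failed
    if (verbose)
      message(sprintf(
        "condition %d/%d (N=%d, noise=%g%%, sparsity=%g %s): TPR=%.2f FPR=%.2f (%d ok, %d failed)",
        ci, nrow(conds), cond$length, cond$noise_percent,
        cond$sparsity_alpha, cond$sparsity_mode,
        results$tpr[ci], results$fpr[ci], ok, failed))
  }

  decisions <- do.call(rbind, lapply(decisions, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- structure(list(results = results, decisions = decisions,
                        config = config),
                   class = "bench_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    write.csv(decisions, file.path(out_dir, "decisions.csv"), row.names = FALSE)
    manifest <- config
    manifest$rossler <- unclass(manifest$rossler)
    manifest$ccc_params <- if (!is.null(manifest$ccc_params)) unclass(manifest$ccc_params)
    manifest$cmi_params <- if (!is.null(manifest$cmi_params)) unclass(manifest$cmi_params)
    jsonlite::write_json(list(timestamp = format(Sys.time()),
                              config = unclass(manifest)),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  out
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("<bench_result> measure = %s, %d realizations x %d surrogates\n",
              x$config$measure, x$config$n_realizations,
              x$config$n_surrogates))
  print(x$results, ...)
  invisible(x)
}

#' Read a time series from a CSV file
#'
#' Accepts one- or two-column CSV (UTF-8, '.' decimal separator, header
#' optional).  With two columns the first is treated as a time stamp and
#' ignored for analysis.  Empty cells and NA tokens are treated as missing
#' samples: they are dropped and the remainder concatenated, with a
#' warning.
#'
#' @param path file path.
#' @return A numeric vector.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE,;\\s]+$", first)
  df <- read.csv(path, header = has_header,
                 na.strings = c("NA", "NaN", "nan", ""))
  if (ncol(df) > 2L)
    stop("expected one or two columns (optional time column + values)",
         call. = FALSE)
  v <- df[[ncol(df)]]
  if (!is.numeric(v))
    stop(sprintf("non-numeric values in '%s'", path), call. = FALSE)
  if (anyNA(v)) {
    warning(sprintf("%d missing values in '%s' dropped (remainder concatenated)",
                    sum(is.na(v)), path), call. = FALSE)
    v <- v[!is.na(v)]
  }
  as.numeric(v)
}

#' Surrogate-tested causality analysis of a pair of series files
#'
#' User-facing entry point mirroring the real-data protocol: reads two
#' CSV series, runs the chosen measure in both directions with surrogate
#' significance testing (stationary bootstrap by default, the protocol
#' for irregularly sampled records) and returns — optionally writes — a
#' report of values, z-scores and decisions.
#'
#' @param x_file,y_file CSV paths (see [read_series_csv()]).  The series
#'   must be pre-aligned; no interpolation is attempted.
#' @param measure,n_surr,surrogate_method,ccc_params,cmi_params,m,eta_x,eta_y,alpha,seed
#'   passed to [causality_significance()].
#' @param out_prefix optional path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return A data frame report (one row per direction) with the full
#'   [causality_significance()] result attached as attribute `"test"`.
#' @export
run_pair_analysis <- function(x_file, y_file, measure = "pccc",
                              n_surr = 100,
                              surrogate_method = "stationary_bootstrap",
                              ccc_params = NULL, cmi_params = NULL,
                              m = 3, eta_x = 1, eta_y = eta_x,
                              alpha = 0.05, seed = NULL,
                              out_prefix = NULL) {
  x <- read_series_csv(x_file)
  y <- read_series_csv(y_file)
  n <- min(length(x), length(y))
  if (length(x) != length(y)) {
    warning(sprintf("series lengths differ (%d, %d); truncating to %d",
                    length(x), length(y), n), call. = FALSE)
    x <- x[seq_len(n)]; y <- y[seq_len(n)]
  }
  res <- causality_significance(x, y, measure = measure, n_surr = n_surr,
                                surrogate_method = surrogate_method,
                                ccc_params = ccc_params,
                                cmi_params = cmi_params,
                                m = m, eta_x = eta_x, eta_y = eta_y,
                                alpha = alpha, seed = seed)
  report <- data.frame(
    direction = c("x_to_y", "y_to_x"),
    measure = measure,
    value = c(res$x_to_y$signed_original %||% res$x_to_y$original_value,
              res$y_to_x$signed_original %||% res$y_to_x$original_value),
    surrogate_mean = c(mean(res$x_to_y$surrogate_values),
                       mean(res$y_to_x$surrogate_values)),
    surrogate_sd = c(sd(res$x_to_y$surrogate_values),
                     sd(res$y_to_x$surrogate_values)),
    z_score = c(res$x_to_y$z_score, res$y_to_x$z_score),
    significant = c(res$x_to_y$significant, res$y_to_x$significant),
    alpha = alpha, n_surrogates = n_surr,
    surrogate_method = surrogate_method,
    stringsAsFactors = FALSE)
  if (!is.null(out_prefix)) {
    write.csv(report, paste0(out_prefix, ".csv"), row.names = FALSE)
    jsonlite::write_json(report, paste0(out_prefix, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(report, "test") <- res
  report
}

#' Shipped parameter presets
#'
#' Named parameter sets for the benchmark and the real-data protocols:
#' window geometries, bin counts, embedding delays and prediction
#' horizons per dataset family.
#'
#' @return A named list; each entry holds `m`, per-series `eta`, a `ccc`
#'   and a `pccc` [ccc_params()] and a `cmi` [cmi_params()].
#' @examples
#' names(benchmark_presets())
#' benchmark_presets()[["rossler"]]$pccc
#' @export
benchmark_presets <- function() {
  list(
    rossler = list(
      m = 3, eta_x = 5, eta_y = 5,
      ccc = ccc_params(L = 300, w = 30, delta = 30, B = 8),
      pccc = ccc_params(L = 25, w = 15, delta = 20, B = factorial(3)),
      cmi = cmi_params(tau = 20, m = 3, eta = 5)),
    `millenial-co2-temp` = list(
      m = 3, eta_x = 11, eta_y = 16,
      ccc = ccc_params(L = 60, w = 15, delta = 20, B = 4),
      pccc = ccc_params(L = 60, w = 30, delta = 20, B = factorial(3)),
      cmi = cmi_params(tau = 1:30, m = 3, eta = 11)),
    `kiloyear-co2-temp` = list(
      m = 3, eta_x = 24, eta_y = 8,
      ccc = ccc_params(L = 60, w = 15, delta = 20, B = 4),
      pccc = ccc_params(L = 30, w = 15, delta = 20, B = factorial(3)),
      cmi = cmi_params(tau = 1:30, m = 3, eta = 24)),
    `kiloyear-ch4-temp` = list(
      m = 3, eta_x = 10, eta_y = 8,
      ccc = ccc_params(L = 60, w = 15, delta = 20, B = 4),
      pccc = ccc_params(L = 30, w = 15, delta = 20, B = factorial(3)),
      cmi = cmi_params(tau = 1:30, m = 3, eta = 10)),
    `monthly-co2-temp` = list(
      m = 3, eta_x = 3, eta_y = 2,
      ccc = ccc_params(L = 60, w = 15, delta = 20, B = 4),
      pccc = ccc_params(L = 30, w = 15, delta = 20, B = factorial(3)),
      cmi = cmi_params(tau = 1:30, m = 3, eta = 3)),
    `yearly-enso-sasm` = list(
      m = 3, eta_x = 1, eta_y = 4,
      ccc = ccc_params(L = 60, w = 15, delta = 20, B = 4),
      pccc = ccc_params(L = 60, w = 30, delta = 30, B = factorial(3)),
      cmi = cmi_params(tau = 1:30, m = 3, eta = 1)),
    `monthly-nino-monsoon` = list(
      m = 3, eta_x = 10, eta_y = 3,
      ccc = ccc_params(L = 60, w = 15, delta = 20, B = 4),
      pccc = ccc_params(L = 30, w = 15, delta = 20, B = factorial(3)),
      cmi = cmi_params(tau = 1:30, m = 3, eta = 10)),
    `monthly-nao-temp` = list(
      m = 3, eta_x = 1, eta_y = 1,
      ccc = ccc_params(L = 60, w = 15, delta = 20, B = 4),
      pccc = ccc_params(L = 30, w = 15, delta = 10, B = factorial(3)),
      cmi = cmi_params(tau = 1:30, m = 3, eta = 1)),
    `daily-nao-temp` = list(
      m = 3, eta_x = 15, eta_y = 15,
      ccc = ccc_params(L = 40, w = 15, delta = 20, B = 4),
      pccc = ccc_params(L = 30, w = 15, delta = 20, B = factorial(3)),
      cmi = cmi_params(tau = 1:30, m = 3, eta = 15)))
}
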