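# Seed handling: every stochastic entry point takes an optional integer seed
# and evaluates under it without disturbing the caller's RNG stream.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based seed spawning: a master seed deterministically yields a
# vector of child seeds (all < 2^31) so that any subset of a sweep can be
# reproduced in isolation.
seed_stream <- function(master, n) {
  if (is.null(master)) return(rep(list(NULL), n))
  as.list(with_seed(master, sample.int(.Machine$integer.max - 1L, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_numeric_series <- function(series, arg = "series") {
  if (!is.numeric(series) || length(series) < 1L)
    stop(sprintf("`%s` must be a non-empty numeric vector", arg), call. = FALSE)
  if (any(!is.finite(series)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  as.numeric(series)
}
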