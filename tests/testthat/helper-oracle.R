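# Independent brute-force oracles, deliberately written with different
# mechanics (string keys, explicit position scans) than the package's
# compiled implementation.

# Greedy non-overlapping occurrence positions of the ordered pair (a, b).
oracle_pair_positions <- function(s, a, b) {
  hits <- which(s[-length(s)] == a & s[-1L] == b)
  kept <- integer(0)
  last_end <- -1L
  for (i in hits) {
    if (i > last_end) {
      kept <- c(kept, i)
      last_end <- i + 1L
    }
  }
  kept
}

# One NSRPS pass: most frequent pair, ties to the pair whose first counted
# occurrence comes earliest in the sequence.
oracle_nsrps <- function(s) {
  pairs <- unique(cbind(s[-length(s)], s[-1L]))
  occ <- lapply(seq_len(nrow(pairs)), function(i)
    oracle_pair_positions(s, pairs[i, 1L], pairs[i, 2L]))
  counts <- lengths(occ)
  firsts <- vapply(occ, `[`, integer(1), 1L)
  best_i <- order(-counts, firsts)[1L]
  best <- pairs[best_i, ]
  pos <- occ[[best_i]]
  fresh <- max(s) + 1L
  out <- integer(0)
  i <- 1L
  while (i <= length(s)) {
    if (i %in% pos) {
      out <- c(out, fresh)
      i <- i + 2L
    } else {
      out <- c(out, s[i])
      i <- i + 1L
    }
  }
  out
}

oracle_etc <- function(s) {
  steps <- 0L
  while (length(s) > 1L && length(unique(s)) > 1L) {
    s <- oracle_nsrps(s)
    steps <- steps + 1L
  }
  steps
}

oracle_joint_etc <- function(a, b) {
  key <- paste(a, b, sep = "|")
  oracle_etc(as.integer(factor(key, levels = unique(key))) - 1L)
}

# Plug-in entropies straight off a contingency table of string keys.
oracle_entropy <- function(...) {
  key <- do.call(paste, c(list(...), sep = "|"))
  tab <- table(key)
  p <- as.numeric(tab) / sum(tab)
  -sum(ifelse(p > 0, p * log(p), 0))
}

oracle_cmi <- function(x, y, z_cols) {
  zkey <- do.call(paste, c(z_cols, sep = "|"))
  oracle_entropy(x, zkey) + oracle_entropy(y, zkey) -
    oracle_entropy(x, y, zkey) - oracle_entropy(zkey)
}

# Binned auto-MI curve via cut() on quantile edges.
oracle_auto_mi_curve <- function(x, max_lag, Q = 16) {
  edges <- unique(quantile(x, probs = (0:Q) / Q))
  sym <- as.integer(cut(x, edges, include.lowest = TRUE))
  n <- length(sym)
  vapply(0:max_lag, function(k) {
    a <- sym[1:(n - k)]
    b <- sym[(1 + k):n]
    oracle_entropy(a) + oracle_entropy(b) - oracle_entropy(a, b)
  }, numeric(1))
}

# Stable rank pattern (value, then position) and its lexicographic index.
oracle_ordinal_pattern <- function(v) rank(v, ties.method = "first") - 1L

oracle_lex_index <- function(pattern) {
  m <- length(pattern)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  all_p <- perms(0:(m - 1L))
  which(vapply(all_p, identical, logical(1), y = as.integer(pattern))) - 1L
}

# Enumerate all binary sequences of a given length as rows.
all_binary <- function(len) {
  as.matrix(expand.grid(rep(list(0:1), len)))[, len:1, drop = FALSE]
}
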