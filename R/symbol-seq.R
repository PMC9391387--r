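#' Finite-alphabet symbol sequences
#'
#' A `symbol_seq` is the substrate on which the effort-to-compress (ETC)
#' complexity, compression-complexity causality and all plug-in entropies
#' operate: an integer vector with symbols in `0 ... alphabet_size - 1`.
#'
#' @param symbols integer vector of non-negative symbols.
#' @param alphabet_size number of admissible symbols; defaults to
#'   `max(symbols) + 1`.
#'
#' @return An integer vector of class `"symbol_seq"` with an
#'   `alphabet_size` attribute.
#' @examples
#' symbol_seq(c(0, 1, 0, 1))
#' symbol_seq(c(0, 2), alphabet_size = 4)
#' @export
symbol_seq <- function(symbols, alphabet_size = NULL) {
  if (length(symbols) < 1L) stop("symbol sequence must be non-empty", call. = FALSE)
  if (any(!is.finite(symbols)) || any(symbols < 0) || any(symbols != floor(symbols)))
    stop("symbols must be non-negative integers", call. = FALSE)
  symbols <- as.integer(symbols)
  alphabet_size <- as.integer(alphabet_size %||% (max(symbols) + 1L))
  if (alphabet_size < 1L || any(symbols >= alphabet_size))
    stop("every symbol must be smaller than `alphabet_size`", call. = FALSE)
  structure(symbols, alphabet_size = alphabet_size, class = "symbol_seq")
}

#' @export
print.symbol_seq <- function(x, ...) {
  cat(sprintf("<symbol_seq> length %d, alphabet size %d\n",
              length(x), alphabet_size(x)))
  print(as.integer(x), ...)
  invisible(x)
}

#' Alphabet size of a symbol sequence
#'
#' @param x a [symbol_seq()] (or an integer vector, in which case
#'   `max(x) + 1` is inferred).
#' @return Integer count of admissible symbols.
#' @export
alphabet_size <- function(x) {
  a <- attr(x, "alphabet_size")
  if (!is.null(a)) return(as.integer(a))
  as.integer(max(as.integer(x)) + 1L)
}

# Coerce plain integer vectors leniently; used at internal boundaries.
as_symbol_seq <- function(x, alphabet_size = NULL) {
  if (inherits(x, "symbol_seq") && is.null(alphabet_size)) return(x)
  symbol_seq(unclass(x), alphabet_size %||% attr(x, "alphabet_size"))
}

# Concatenation keeps the larger alphabet (windows of one series share it).
concat_symbols <- function(a, b) {
  symbol_seq(c(as.integer(a), as.integer(b)),
             max(alphabet_size(a), alphabet_size(b)))
}
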