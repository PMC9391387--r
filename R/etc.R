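#' Effort-to-compress (ETC) complexity
#'
#' ETC measures the complexity of a finite-alphabet sequence as the number
#' of Non-Sequential Recursive Pair Substitution (NSRPS) iterations needed
#' to reduce it to a constant or length-1 sequence.  Each iteration
#' replaces the most frequent adjacent symbol pair (counted non-overlapping,
#' left to right; ties broken by the earliest first occurrence, a
#' positional rule that keeps the step count exactly invariant under
#' alphabet relabeling) with a fresh symbol.  A constant sequence has ETC
#' 0; a fully incompressible sequence of length `L` needs at most `L - 1`
#' iterations.
#'
#' @param seq a [symbol_seq()] or non-negative integer vector.
#'
#' @return A list of class `"etc_result"` with `steps` (the ETC value) and
#'   `normalized` (`steps / (L - 1)`, defined as 0 for `L = 1`).
#' @examples
#' etc(symbol_seq(c(0, 1, 0, 1)))$steps          # "0101" -> "22": 1 step
#' etc(symbol_seq(c(0, 1, 0, 1, 1, 1)))$steps    # 4 steps
#' @export
etc <- function(seq) {
  seq <- as_symbol_seq(seq)
  L <- length(seq)
  steps <- cpp_etc_steps(as.integer(seq), alphabet_size(seq))
  structure(list(steps = steps,
                 normalized = if (L > 1L) steps / (L - 1) else 0),
            class = "etc_result")
}

#' @export
print.etc_result <- function(x, ...) {
  cat(sprintf("<etc_result> steps = %d, normalized = %.4f\n",
              x$steps, x$normalized))
  invisible(x)
}

#' Single NSRPS substitution pass
#'
#' Performs one pair-substitution iteration of the ETC algorithm: the most
#' frequent adjacent pair (non-overlapping greedy count, ties to the
#' earliest first occurrence) is replaced by a fresh symbol appended to
#' the alphabet.
#'
#' @param seq a [symbol_seq()] of length >= 2 (a constant run still
#'   contains its repeated pair; only a length-1 sequence is irreducible).
#' @return A strictly shorter [symbol_seq()] with alphabet grown by one.
#' @examples
#' nsrps_step(symbol_seq(c(0, 1, 0, 1)))   # -> "2 2"
#' nsrps_step(symbol_seq(c(0, 1, 1, 0)))   # tie -> (0,1) -> "2 1 0"
#' @export
nsrps_step <- function(seq) {
  seq <- as_symbol_seq(seq)
  out <- cpp_nsrps_step(as.integer(seq), alphabet_size(seq))
  symbol_seq(out$seq, alphabet_size = out$alphabet_size)
}

#' Joint (two-sequence) effort-to-compress
#'
#' Codes the pair sequence `(a_t, b_t)` onto a product alphabet (observed
#' pairs numbered in first-appearance order) and applies [etc()].  Used by
#' the joint compression-complexity term of CCC.
#'
#' @param a,b equal-length [symbol_seq()] objects.
#' @return An `"etc_result"` as for [etc()].
#' @examples
#' joint_etc(symbol_seq(0:1), symbol_seq(0:1))$steps  # relabeling of "01"
#' @export
joint_etc <- function(a, b) {
  a <- as_symbol_seq(a); b <- as_symbol_seq(b)
  if (length(a) != length(b))
    stop("joint ETC requires equal-length sequences", call. = FALSE)
  L <- length(a)
  steps <- cpp_joint_etc_steps(as.integer(a), as.integer(b))
  structure(list(steps = steps,
                 normalized = if (L > 1L) steps / (L - 1) else 0),
            class = "etc_result")
}
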