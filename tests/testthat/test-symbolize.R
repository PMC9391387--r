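test_that("delay embedding produces the documented vectors and counts", {
  e <- delay_embed(1:5, m = 3, eta = 1)
  expect_equal(nrow(e), 3L)
  expect_equal(unclass(e)[1, ], c(1, 2, 3))
  expect_equal(unclass(e)[3, ], c(3, 4, 5))

  e2 <- delay_embed(1:5, m = 3, eta = 2)
  expect_equal(nrow(e2), 1L)
  expect_equal(unclass(e2)[1, ], c(1, 3, 5))

  # count is forced arithmetic: N - (m-1)*eta
  x <- rnorm(500)
  expect_equal(nrow(delay_embed(x, m = 3, eta = 5)), 500L - 10L)

  expect_error(delay_embed(1:4, m = 3, eta = 2), "insufficient length")
})

test_that("backward embedding mirrors forward offsets and records alignment", {
  x <- as.numeric(1:10)
  f <- delay_embed(x, m = 3, eta = 2, direction = "forward")
  b <- delay_embed(x, m = 3, eta = 2, direction = "backward")
  expect_equal(attr(f, "t0"), 0L)
  expect_equal(attr(b, "t0"), 4L)
  # first backward vector is anchored at t = (m-1)*eta: (x5, x3, x1)
  expect_equal(unclass(b)[1, ], c(5, 3, 1))
  expect_equal(nrow(b), nrow(f))
})

test_that("ordinal encoding ranks ascending with ties by occurrence order", {
  # worked triple: (3,5,5), (3,3,5), (3,3,3) all give pattern (0,1,2)
  v <- matrix(c(3, 5, 5, 3, 3, 5, 3, 3, 3), ncol = 3, byrow = TRUE)
  sym <- ordinal_encode(v)
  expect_equal(as.integer(sym), c(0L, 0L, 0L))
  expect_equal(alphabet_size(sym), 6L)

  expect_equal(as.integer(ordinal_encode(matrix(c(1, 2, 3), 1))), 0L)

  # (5,3,4) -> pattern (2,0,1); cross-check the integer code with the
  # stable-rank + permutation-enumeration oracle
  p <- oracle_ordinal_pattern(c(5, 3, 4))
  expect_equal(p, c(2L, 0L, 1L))
  expect_equal(as.integer(ordinal_encode(matrix(c(5, 3, 4), 1))),
               oracle_lex_index(p))
})

test_that("ordinal pattern integer codes agree with the enumeration oracle", {
  set.seed(7)
  for (m in 2:4) {
    v <- matrix(sample(1:4, 40 * m, replace = TRUE), ncol = m)
    sym <- ordinal_encode(v)
    expect_lte(max(as.integer(sym)), factorial(m) - 1L)
    expected <- vapply(seq_len(nrow(v)), function(i)
      oracle_lex_index(oracle_ordinal_pattern(v[i, ])), integer(1))
    expect_equal(as.integer(sym), expected)
  }
})

test_that("ordinal encoding is invariant under strictly monotonic transforms", {
  set.seed(11)
  x <- rnorm(300)
  e <- function(s) as.integer(ordinal_encode(delay_embed(s, 3, 2)))
  expect_equal(e(exp(x)), e(x))
  expect_equal(e(2 * x + 7), e(x))
  expect_equal(e(x^3), e(x))
})

test_that("equidistant binning uses right-closed top bin and global edges", {
  expect_equal(as.integer(equidistant_bin(c(0, 0.5, 1), B = 2)), c(0L, 1L, 1L))
  expect_equal(as.integer(equidistant_bin(rep(3.7, 10), B = 5)), rep(0L, 10))
  s <- equidistant_bin(rnorm(100), B = 6)
  expect_equal(alphabet_size(s), 6L)
  expect_error(equidistant_bin(c(1, NA, 2), B = 2), "non-finite")
})

test_that("amplitude binning is invariant under positive affine transforms", {
  set.seed(3)
  x <- rnorm(500)
  expect_equal(as.integer(equidistant_bin(3 * x + 2, 8)),
               as.integer(equidistant_bin(x, 8)))
  expect_equal(as.integer(equiquantal_bin(3 * x + 2, 8)),
               as.integer(equiquantal_bin(x, 8)))
})

test_that("equiquantal binning balances counts and handles few distinct values", {
  counts <- table(as.integer(equiquantal_bin(1:100, Q = 4)))
  expect_equal(as.vector(counts), rep(25L, 4))

  # 8 distinct values with Q = 8 is an identity ranking
  v <- c(5, 1, 8, 3, 7, 2, 6, 4)
  expect_equal(as.integer(equiquantal_bin(v, Q = 8)), order(order(v)) - 1L)

  expect_error(equiquantal_bin(rep(c(1, 2), 10), Q = 4), "distinct")

  set.seed(9)
  g <- rnorm(1e5)
  freq <- tabulate(as.integer(equiquantal_bin(g, 8)) + 1L, 8) / 1e5
  expect_true(all(abs(freq - 1 / 8) < 0.01))
})

test_that("iid series populate all m! ordinal patterns uniformly", {
  set.seed(21)
  x <- runif(1e5)
  sym <- ordinal_encode(delay_embed(x, m = 3, eta = 1))
  counts <- tabulate(as.integer(sym) + 1L, 6L)
  expect_equal(length(counts[counts > 0]), 6L)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("first auto-MI minimum recovers the quarter period of a noisy sinusoid", {
  set.seed(42)
  x <- sin(2 * pi * (1:4000) / 20) + rnorm(4000, 0, 0.2)
  lag <- select_delay_auto_mi(x, max_lag = 15)
  expect_equal(as.integer(lag), 5L)
  expect_true(attr(lag, "local_minimum"))
  # the oracle curve has its first interior dip at the same lag
  curve <- oracle_auto_mi_curve(x, 15)
  dips <- which(curve[2:15] < curve[1:14] & curve[2:15] < curve[3:16])
  expect_equal(dips[1], 5L)
})

test_that("auto-MI delay for iid noise is immediate and preconditions hold", {
  set.seed(8)
  x <- runif(10000)
  lag <- suppressWarnings(select_delay_auto_mi(x, max_lag = 10))
  expect_lte(as.integer(lag), 2L)
  expect_error(select_delay_auto_mi(x, max_lag = 1), "max_lag")
  expect_error(select_delay_auto_mi(rep(1, 100), max_lag = 5), "constant")
})
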