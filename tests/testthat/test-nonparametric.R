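# Tests of the self-contained rank tests against direct-formula and
# exact-enumeration oracles, and against the base-R implementations where
# the conventions coincide (no ties, exact p).

test_that("signed-rank test: exact enumeration on canonical small cases", {
  # n = 3, all differences positive, no ties: one-tailed 1/8, two-tailed 1/4
  r <- wilcoxon_signed_rank(c(2, 3, 5), c(1, 1, 1))
  expect_equal(r$statistic, 6)
  expect_true(r$exact)
  expect_equal(r$p_two_tailed, 0.25)
  # matches base R's exact signed-rank p in the tie-free regime
  b <- wilcox.test(c(2, 3, 5), c(1, 1, 1), paired = TRUE, exact = TRUE)
  expect_equal(r$p_two_tailed, b$p.value)
})

test_that("signed-rank test: symmetric differences give Z = 0", {
  r <- wilcoxon_signed_rank(c(1, -1, 2.5, -2.5))
  expect_equal(r$z_adjusted, 0)
})

test_that("signed-rank test: degenerate and tie-corrected paths", {
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")
  x <- c(3, 3, 5, 7, 7, 9, 2, 4)
  y <- c(1, 1, 2, 2, 2, 2, 3, 1)
  r <- wilcoxon_signed_rank(x, y)
  expect_true(r$ties_present)
  expect_equal(r$z_adjusted, oracle_wilcoxon_z(x, y), tolerance = 1e-12)
})

test_that("signed-rank normal approximation tracks the enumeration p for n in 6..12", {
  set.seed(11)
  for (n in 6:12) {
    x <- round(rnorm(n, 0.4), 1)
    x <- x[x != 0]
    if (length(x) < 2) next
    r <- wilcoxon_signed_rank(x)
    expect_true(r$exact)
    # the discrete exact p and the normal p agree loosely at these n and
    # increasingly well as n grows
    expect_lt(abs(r$p_normal - r$p_two_tailed), if (length(x) >= 10) 0.06 else 0.12)
  }
})

test_that("Mann-Whitney: separated samples give extreme U and exact p", {
  r <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$statistic, 0)       # min(U1, U2); U1 = 9 here
  expect_equal(r$u1, 9)
  expect_equal(r$p_two_tailed, 2 / choose(6, 3))
  b <- wilcox.test(c(4, 5, 6), c(1, 2, 3), exact = TRUE)
  expect_equal(r$p_two_tailed, b$p.value)
})

test_that("Mann-Whitney: identical multisets give U = nm/2 and Z = 0", {
  r <- mann_whitney_u(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$u1, 4.5)
  expect_equal(r$z_adjusted, 0)
  expect_error(mann_whitney_u(c(2, 2), c(2, 2)), "degenerate")
})

test_that("Mann-Whitney: tie-corrected Z matches the direct formula", {
  set.seed(5)
  for (rep in 1:10) {
    x <- sample(1:4, 5, replace = TRUE)
    y <- sample(1:4, 5, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    r <- mann_whitney_u(x, y)
    expect_equal(r$z_adjusted, oracle_mwu_z(x, y), tolerance = 1e-12)
    expect_true(r$exact)    # the p itself comes from enumeration here
  }
})

test_that("rank tests are invariant under monotone relabelling", {
  set.seed(21)
  x <- rnorm(7); y <- rnorm(6)
  f <- function(v) exp(v) + 3          # strictly increasing
  expect_equal(mann_whitney_u(x, y)$u1, mann_whitney_u(f(x), f(y))$u1)
  expect_equal(ks_two_sample(x, y)$statistic, ks_two_sample(f(x), f(y))$statistic)
})

test_that("KS: identity, disjoint supports, and staircase fixture", {
  expect_equal(ks_two_sample(1:6, 1:6)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$statistic, 1)
  x <- c(1, 1, 2, 4, 4, 7); y <- c(2, 3, 3, 5, 8)
  r <- ks_two_sample(x, y)
  expect_equal(r$statistic, oracle_ks_d(x, y))
  expect_equal(r$statistic, unname(ks.test(x, y)$statistic))
})

test_that("kappa: perfect, independent and averaged agreement", {
  a <- rep(c("x", "y", "z"), 10)
  expect_equal(cohen_kappa(a, a)$kappa, 1)
  set.seed(9)
  b1 <- sample(c("x", "y"), 4000, replace = TRUE)
  b2 <- sample(c("x", "y"), 4000, replace = TRUE)
  expect_lt(abs(cohen_kappa(b1, b2)$kappa), 0.05)
  expect_error(average_kappa(c(0.5, 1.2)), "at most 1")
})
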