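#' Nonparametric tests with tie correction and exact small-sample p-values
#'
#' Self-contained rank tests used throughout the post-conflict pipeline:
#' the Wilcoxon matched-pair signed-ranks test, the Mann-Whitney U test
#' and the two-sample Kolmogorov-Smirnov test. All ranking uses mid-ranks
#' for ties and the normal deviate is tie-corrected ("Z adjusted"). For
#' desk-scale samples an exact p-value is obtained by complete enumeration
#' of the permutation distribution (all sign patterns for the signed-rank
#' test, all group assignments for the U test), so the normal approximation
#' can always be checked against the exact reference at small n.
#'
#' @name pcmc-nonparametric
#' @keywords internal
NULL

new_test_result <- function(statistic_name, statistic, z, p, n, m = NA_integer_,
                            ties_present = FALSE, exact = FALSE, extra = list()) {
  out <- c(list(
    statistic_name = statistic_name,
    statistic = unname(statistic),
    z_adjusted = unname(z),
    p_two_tailed = unname(min(1, p)),
    n = n, m = m,
    ties_present = ties_present,
    exact = exact
  ), extra)
  class(out) <- "pcmc_test"
  out
}

#' @export
print.pcmc_test <- function(x, ...) {
  cat(sprintf("%s = %.4g", x$statistic_name, x$statistic))
  if (is.finite(x$z_adjusted)) cat(sprintf(", Z adj = %.4f", x$z_adjusted))
  cat(sprintf(", p (two-tailed%s) = %.4g\n",
              if (isTRUE(x$exact)) ", exact" else "", x$p_two_tailed))
  ns <- if (is.na(x$m)) sprintf("n = %d", x$n) else sprintf("n = %d, m = %d", x$n, x$m)
  cat(sprintf("  %s%s\n", ns, if (isTRUE(x$ties_present)) " (ties present)" else ""))
  invisible(x)
}

two_tailed_from_tail <- function(p_lower, p_upper) {
  min(1, 2 * min(p_lower, p_upper))
}

#' Wilcoxon matched-pair signed-ranks test, corrected for ties
#'
#' Computes the signed-rank statistic W+ on the paired differences, the
#' tie-corrected normal deviate
#' \deqn{Z = \frac{W^+ - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum(t^3 - t)/48}}}
#' and a two-tailed p-value. Zero differences are dropped by default (the
#' classic Wilcoxon convention); `zero_method = "pratt"` instead ranks them
#' with the rest and then discards their ranks. When the number of nonzero
#' differences is at most `exact_limit` the two-tailed p-value is computed
#' exactly by enumerating all 2^n sign assignments of the observed ranks.
#'
#' @param x numeric vector; first member of each pair, or the differences
#'   themselves if `y` is `NULL`.
#' @param y optional numeric vector paired with `x`.
#' @param zero_method `"wilcoxon"` (drop zero differences) or `"pratt"`.
#' @param continuity logical; apply a 0.5 continuity correction to Z.
#' @param exact_limit maximum n for complete sign-pattern enumeration.
#' @return a `pcmc_test` object with fields `statistic` (W+), `z_adjusted`,
#'   `p_two_tailed`, `n` (nonzero pairs), `ties_present`, `exact`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 5), c(1, 1, 1))
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, zero_method = c("wilcoxon", "pratt"),
                                 continuity = FALSE, exact_limit = 12L) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  if (length(d) == 0L || all(d == 0)) {
    stop("degenerate: no nonzero differences", call. = FALSE)
  }
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w_plus <- sum(r[d > 0])
  mu <- sum(r) / 2                       # n(n+1)/4 when no zeros are kept
  tie_tab <- table(r)
  ties <- any(tie_tab > 1)
  t_sizes <- as.numeric(tie_tab)
  sigma2 <- sum(r^2) / 4                 # equals n(n+1)(2n+1)/24 - sum(t^3-t)/48
  if (sigma2 <= 0) stop("degenerate: zero variance", call. = FALSE)
  num <- w_plus - mu
  if (continuity) num <- sign(num) * max(0, abs(num) - 0.5)
  z <- num / sqrt(sigma2)
  exact <- n <= exact_limit
  if (exact) {
    dist <- signrank_enumerate(r)
    p_lower <- sum(dist[dist[, 1] <= w_plus + 1e-9, 2])
    p_upper <- sum(dist[dist[, 1] >= w_plus - 1e-9, 2])
    p <- two_tailed_from_tail(p_lower, p_upper)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_test_result("W+", w_plus, z, p, n, ties_present = ties, exact = exact,
                  extra = list(p_normal = min(1, 2 * stats::pnorm(-abs(z)))))
}

# Exact null distribution of W+ = sum of ranks with positive sign, for the
# given (possibly tied mid-)ranks; returns a two-column matrix (value, prob).
signrank_enumerate <- function(ranks) {
  n <- length(ranks)
  stopifnot(n <= 24)
  vals <- 0
  for (r in ranks) vals <- c(vals, vals + r)   # subset sums, 2^n of them
  tab <- table(vals)
  cbind(as.numeric(names(tab)), as.numeric(tab) / length(vals))
}

#' Mann-Whitney U test with tie-corrected normal deviate
#'
#' Rank-sum test for two independent samples. U is reported as the smaller
#' of U1 and U2; the normal deviate uses the tie-corrected variance
#' \deqn{\sigma^2_U = \frac{nm}{12}\left[(N+1) - \frac{\sum(t^3-t)}{N(N-1)}\right].}
#' For `length(x) + length(y) <= exact_limit` the p-value is exact, by
#' enumeration of all group assignments of the pooled (mid-)ranks.
#'
#' @param x,y numeric samples.
#' @param continuity logical; 0.5 continuity correction.
#' @param exact_limit maximum pooled size for exact enumeration.
#' @return a `pcmc_test` with `statistic` = min(U1, U2), `z_adjusted` signed
#'   as U1 - nm/2 (positive when `x` tends to exceed `y`), and `u1`, `u2`
#'   in the extra fields.
#' @examples
#' mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
#' @export
mann_whitney_u <- function(x, y, continuity = FALSE, exact_limit = 12L) {
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty", call. = FALSE)
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) stop("degenerate: zero variance", call. = FALSE)
  r <- rank(pooled)
  r1 <- sum(r[seq_len(n)])
  u1 <- r1 - n * (n + 1) / 2
  u2 <- n * m - u1
  tie_tab <- table(pooled)
  ties <- any(tie_tab > 1)
  t_sizes <- as.numeric(tie_tab)
  sigma2 <- n * m / 12 * ((N + 1) - sum(t_sizes^3 - t_sizes) / (N * (N - 1)))
  if (sigma2 <= 0) stop("degenerate: zero variance", call. = FALSE)
  num <- u1 - n * m / 2
  if (continuity) num <- sign(num) * max(0, abs(num) - 0.5)
  z <- num / sqrt(sigma2)
  exact <- N <= exact_limit
  if (exact) {
    dist <- mwu_enumerate(r, n)
    p_lower <- sum(dist[dist[, 1] <= u1 + 1e-9, 2])
    p_upper <- sum(dist[dist[, 1] >= u1 - 1e-9, 2])
    p <- two_tailed_from_tail(p_lower, p_upper)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_test_result("U", min(u1, u2), z, p, n, m, ties_present = ties, exact = exact,
                  extra = list(u1 = u1, u2 = u2,
                               p_normal = min(1, 2 * stats::pnorm(-abs(z)))))
}

# Exact null distribution of U1 given pooled mid-ranks and first-group size.
mwu_enumerate <- function(pooled_ranks, n) {
  combos <- utils::combn(length(pooled_ranks), n)
  u_vals <- apply(combos, 2, function(idx) sum(pooled_ranks[idx]) - n * (n + 1) / 2)
  tab <- table(round(u_vals, 9))
  cbind(as.numeric(names(tab)), as.numeric(tab) / ncol(combos))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference of the two empirical distribution
#' functions, evaluated by a direct scan over the pooled support; the
#' two-tailed p-value uses the asymptotic Kolmogorov series with effective
#' sample size nm/(n+m).
#'
#' @param x,y numeric samples.
#' @return a `pcmc_test` with `statistic` = D and the location of the
#'   supremum in `extra$at`.
#' @examples
#' ks_two_sample(1:5, 6:10)
#' @export
ks_two_sample <- function(x, y) {
  x <- sort(as.numeric(x[!is.na(x)])); y <- sort(as.numeric(y[!is.na(y)]))
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty", call. = FALSE)
  n <- length(x); m <- length(y)
  support <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(support)
  fy <- stats::ecdf(y)(support)
  diffs <- abs(fx - fy)
  d <- max(diffs)
  ne <- n * m / (n + m)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  k <- 1:100
  p <- if (d == 0) 1 else min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  new_test_result("D", d, NA_real_, p, n, m,
                  ties_present = length(unique(c(x, y))) < n + m,
                  extra = list(at = support[which.max(diffs)]))
}

#' Cohen's kappa for inter-observer agreement
#'
#' Chance-corrected agreement between two observers' categorical codings,
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. Besides the overall multi-category
#' kappa, a per-category kappa is computed by collapsing each category
#' against all others; the averaged coefficient is the arithmetic mean of
#' the per-category values (the convention used when agreement is reported
#' per behavioural class).
#'
#' @param codes_a,codes_b equal-length vectors of category labels.
#' @return a list of class `pcmc_kappa`: `kappa` (multi-category),
#'   `per_category` (named vector), `averaged` (mean of per-category
#'   kappas), `n`.
#' @seealso [average_kappa()] to average already-computed coefficients.
#' @export
cohen_kappa <- function(codes_a, codes_b) {
  if (length(codes_a) != length(codes_b)) stop("codings must have equal length", call. = FALSE)
  a <- as.character(codes_a); b <- as.character(codes_b)
  n <- length(a)
  cats <- sort(unique(c(a, b)))
  tab <- table(factor(a, cats), factor(b, cats)) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe <= 0) stop("undefined kappa: chance agreement is 1", call. = FALSE)
  per <- vapply(cats, function(cc) {
    aa <- a == cc; bb <- b == cc
    po_c <- mean(aa == bb)
    pe_c <- mean(aa) * mean(bb) + mean(!aa) * mean(!bb)
    if (1 - pe_c <= 0) return(NA_real_)
    (po_c - pe_c) / (1 - pe_c)
  }, numeric(1))
  out <- list(kappa = (po - pe) / (1 - pe),
              per_category = per,
              averaged = mean(per, na.rm = TRUE),
              n = n)
  class(out) <- "pcmc_kappa"
  out
}

#' @export
print.pcmc_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (n = %d); averaged per-category kappa = %.2f\n",
              x$kappa, x$n, x$averaged))
  invisible(x)
}

#' Average already-computed kappa coefficients
#'
#' The overall averaged agreement coefficient when per-class kappas were
#' obtained separately (e.g. one per behavioural category): their
#' unweighted arithmetic mean.
#'
#' @param kappas numeric vector of kappa coefficients, each at most 1.
#' @return the mean coefficient.
#' @examples
#' average_kappa(c(0.81, 0.74, 0.76, 0.97))
#' @export
average_kappa <- function(kappas) {
  kappas <- as.numeric(kappas)
  if (any(!is.finite(kappas)) || any(kappas > 1)) {
    stop("kappa coefficients must be finite and at most 1", call. = FALSE)
  }
  mean(kappas)
}
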