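#' Friedman omnibus test over a score matrix
#'
#' Nonparametric repeated-measures comparison of k models scored on n
#' paired units (subjects or joints): scores are ranked within each row and
#' the rank sums compared with a chi-square statistic on k - 1 degrees of
#' freedom (ties receive average ranks). Wraps [stats::friedman.test()].
#'
#' @param scores `n x k` matrix; rows = paired units, columns = models.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stopf("need at least 2 models to compare")
  if (nrow(scores) < 2) stopf("need at least 2 paired units")
  ht <- stats::friedman.test(scores)
  stat <- unname(ht$statistic)
  p <- unname(ht$p.value)
  if (!is.finite(stat)) {        # all ranks tied in every row: no evidence
    stat <- 0
    p <- 1
  }
  list(statistic = stat, df = unname(ht$parameter), p_value = p)
}

# Exact pmf of the positive signed-rank sum W+ over all 2^m equiprobable sign
# assignments, with ties in |d| given average ranks. Works on doubled ranks so
# average ranks stay integral. Returns support (doubled) and probabilities.
signed_rank_pmf <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test of model A versus model B scores. Zero differences
#' are dropped (with a warning); ties among the remaining |differences|
#' receive average ranks. For m <= `exact_max` remaining pairs the two-sided
#' p-value is exact, computed from the full distribution of the signed-rank
#' sum over all 2^m sign assignments (so e.g. m = 10 all-positive differences
#' give p = 2/1024 = 0.001953...); beyond that a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param a,b equal-length numeric vectors of paired scores.
#' @param exact_max largest m for which the exact distribution is enumerated.
#' @return list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `exact`, and `n_used` (pairs remaining after dropping zeros).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25L) {
  if (length(a) != length(b)) stopf("a and b must have equal length")
  d <- a - b
  if (any(d == 0)) {
    warnf("dropping %d zero difference(s)", sum(d == 0))
    d <- d[d != 0]
  }
  m <- length(d)
  if (m == 0) stopf("degenerate comparison: all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (m <= exact_max) {
    pmf <- signed_rank_pmf(as.integer(round(2 * r)))
    v2 <- round(2 * V)
    lo <- sum(pmf[seq_len(v2 + 1)])              # P(W+ <= V)
    hi <- sum(pmf[(v2 + 1):length(pmf)])          # P(W+ >= V)
    p <- min(1, 2 * min(lo, hi))
    exact <- TRUE
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = V, p_value = p, exact = exact, n_used = m)
}
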