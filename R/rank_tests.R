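#' Wilcoxon-Mann-Whitney rank-sum test with exact tie-aware enumeration
#'
#' Statistic is the Mann-Whitney U for the *first* group: the number of
#' (x, y) pairs with x > y, counting ties as 1/2 (equivalently the rank sum
#' of `x` with mid-ranked ties minus `n1 (n1 + 1) / 2`). For small samples
#' the two-sided p-value is computed by full enumeration of the
#' `choose(n1 + n2, n1)` group labelings of the pooled mid-ranks (exact even
#' under ties, where the classical tables do not apply); larger samples use
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (first group = `x`).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   enumerates when both groups have at most 10 observations.
#' @return List: `statistic` (U), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  u <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- max(n1, n2) <= 10
  if (exact) {
    combos <- utils::combn(n1 + n2, n1)
    r1 <- matrix(ranks[combos], nrow = n1)
    u_all <- colSums(r1) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(ranks)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- if (sigma2 == 0) 1 else min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    if (u == mu) p <- 1
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Statistic V = sum of the ranks (mid-ranked |differences|) of the
#' positive differences; zero differences are dropped. Exact two-sided
#' p-value by enumeration of all 2^n sign patterns for n <= 14 non-zero
#' differences; normal approximation with tie correction otherwise.
#'
#' @param x,y Paired numeric samples of equal length.
#' @return List: `statistic` (V), `p_value`, `n_used`, `method`.
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1, n_used = 0L,
                          method = "all differences zero"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 14) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p <- mean(abs(v_all - mu) >= abs(v - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(v - mu) - 0.5) / sqrt(sigma2)
    p <- if (sigma2 == 0) 1 else min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = v, p_value = p, n_used = n, method = method)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment via [stats::p.adjust()], with input validation;
#' order of the input vector is preserved.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length.
#' @export
bh_fdr <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
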