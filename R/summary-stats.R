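#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t on group means, SDs and sizes:
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2), with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Useful for recomputing
#' published group comparisons from their printed summaries.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @examples
#' welchTFromSummary(63.11, 14.8, 44, 63.12, 11.2, 100)$t  # ~0
#' @export
welchTFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Pearson chi-square test of independence for a 2 x 2 table
#'
#' Without continuity correction (the convention behind published
#' sex-distribution comparisons).
#'
#' @param counts 2 x 2 matrix of counts.
#' @return list with `X2`, `df` and `p`.
#' @export
chi2Independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(dim(counts) != 2)) stop("counts must be 2 x 2")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) stop("zero marginal: expected counts must be > 0")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(X2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
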