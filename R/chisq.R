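#' Pearson chi-square test of independence
#'
#' Computes the Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the table margins, `df = (r - 1)(c - 1)`, and the upper-tail p-value
#' of the chi-square distribution (the regularized upper incomplete gamma
#' function, via [stats::pchisq()]). No continuity correction is applied.
#'
#' @param table Numeric matrix of counts, at least 2x2, with strictly positive
#'   row and column margins.
#' @return List with `statistic`, `df`, `p`, and `expected`.
#' @export
#'
#' @examples
#' chi_square(matrix(c(20, 5, 5, 20), 2))
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be >= 0")
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("table must be at least 2x2 (df would be 0)")
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  E <- outer(rs, cs) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE), expected = E)
}
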