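#' Pooled two-sample t test with Cohen's d
#'
#' Student's pooled-variance t test (df = n1 + n2 - 2, the convention the
#' printed group comparisons follow) plus the standardized mean difference
#' d = (mean(x) - mean(y)) / pooled sd.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return A one-row tibble: `t`, `df`, `p`, `d`, group means and sizes.
#' @export
group_ttest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 values.")
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) abort("zero pooled variance.")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, d = (mean(x) - mean(y)) / sqrt(sp2),
         mean_x = mean(x), mean_y = mean(y), n1 = n1, n2 = n2)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p value uses the
#' t-distribution approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A one-row tibble: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Spearman needs at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: rho undefined.")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), n - 2)
  }
  tibble(rho = rho, p = p, n = n)
}

#' Compare two correlations via Fisher's r-to-z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p value.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes, each >= 4.
#' @return A one-row tibble: `z`, `p`.
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("|r| must be < 1.")
  if (n1 < 4 || n2 < 4) abort("need n >= 4 in each sample.")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}
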