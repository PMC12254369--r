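#' Row-wise Welch (heteroscedastic) two-sample t-test
#'
#' Single shared implementation of the unequal-variance two-sample t-test
#' used everywhere in the package (protein differential abundance, cohort
#' stratification).  Operates row-wise on matrices so thousands of features
#' are tested in one vectorised pass; p-values are two-tailed with
#' Welch-Satterthwaite degrees of freedom.
#'
#' Degenerate rows where both groups have zero variance are given `t = 0`,
#' `p = 1` when the means agree (no evidence of change) and `p = 0` when
#' they differ (the difference is seen without noise).
#'
#' @param a,b numeric matrices with one row per feature and one column per
#'   replicate (vectors are treated as single-row matrices).  Each must have
#'   at least 2 columns.
#' @return A data frame with columns `estimate` (mean of `a` minus mean of
#'   `b`), `t`, `df` and `p_value`, one row per feature.
#' @examples
#' welch_test(c(10.4, 10.5, 10.3), c(10.0, 10.1, 9.9))
#' @export
welch_test <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1L)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1L)
  if (nrow(a) != nrow(b)) stop_input("welch_test: 'a' and 'b' must have the same number of rows")
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop_input("welch_test needs >=2 replicates per group")
  if (anyNA(a) || anyNA(b)) stop_input("welch_test input contains NA; impute first")

  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  est <- ma - mb

  tstat <- est / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)

  zero <- se2 == 0
  if (any(zero)) {
    tstat[zero] <- ifelse(est[zero] == 0, 0, sign(est[zero]) * Inf)
    df[zero] <- na + nb - 2
    p[zero] <- ifelse(est[zero] == 0, 1, 0)
  }
  data.frame(estimate = est, t = tstat, df = df, p_value = p,
             row.names = rownames(a))
}
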