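#' Quantile-quantile points for p-values
#'
#' Ascending-sorted observed p-values are paired with uniform order-statistic
#' expectations: for rank i of n, expected p is i/(n+1); both are reported on
#' the -log10 scale, sorted by expected value (increasing).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return A data.frame with columns `expected` and `observed`
#'   (-log10 scale), class `QQData`.
#' @export
qq_points <- function(pvalues) {
  if (length(pvalues) < 1) stop("need at least one p-value")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  n <- length(pvalues)
  p_sorted <- sort(pvalues, decreasing = TRUE)   # largest p = smallest -log10
  expected <- -log10(rev(seq_len(n)) / (n + 1))  # increasing
  out <- data.frame(expected = expected, observed = -log10(p_sorted))
  class(out) <- c("QQData", "data.frame")
  out
}

#' Quantile-window genomic inflation factor (lambda 0.5-0.95)
#'
#' Fits a least-squares line through the origin to the QQ points whose
#' expected value lies within the central [0.5, 0.95] quantile window of the
#' expected distribution; lambda is the slope. The window excludes both the
#' deflated head (large p) and the inflated extreme tail, which in sparse
#' collapsing tests is dominated by selection of ultra-rare variants rather
#' than by genome-wide confounding. With fewer than `min_n` points in the
#' window the estimate is unstable and lambda falls back to 1 with a
#' warning.
#'
#' Under the uniform expected distribution the q-quantile of expected
#' -log10(p) is -log10(1 - q), so the window [0.5, 0.95] selects the points
#' whose expected p lies between the 5th and the 50th percentile.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param window Quantile window on the expected distribution,
#'   default `c(0.5, 0.95)`.
#' @param min_n Minimum number of in-window points (default 20).
#' @return A list of class `LambdaEstimate` with `lambda`, `window`,
#'   `n_points_used`, `n_pvalues`, and the `qq` table with an `in_window`
#'   flag.
#' @export
estimate_lambda <- function(pvalues, window = c(0.5, 0.95), min_n = 20) {
  stopifnot(length(window) == 2, window[1] < window[2])
  qq <- qq_points(pvalues)
  n <- nrow(qq)
  # empirical quantile rank of each expected value (they are distinct and
  # increasing): point j of n sits at quantile j/(n+1)
  qrank <- seq_len(n) / (n + 1)
  sel <- qrank >= window[1] & qrank <= window[2]
  qq$in_window <- sel
  est <- structure(list(lambda = 1, window = window,
                        n_points_used = sum(sel), n_pvalues = n, qq = qq),
                   class = "LambdaEstimate")
  if (sum(sel) < min_n) {
    warning("only ", sum(sel), " QQ points in the quantile window (< ",
            min_n, "); lambda set to 1")
    return(est)
  }
  e <- qq$expected[sel]
  o <- qq$observed[sel]
  if (all(e == 0)) stop("all in-window expected values are zero")
  est$lambda <- sum(e * o) / sum(e * e)
  est
}

#' @export
print.LambdaEstimate <- function(x, ...) {
  cat(sprintf("lambda[%.2f-%.2f] = %.4f (%d of %d points)\n",
              x$window[1], x$window[2], x$lambda,
              x$n_points_used, x$n_pvalues))
  invisible(x)
}

#' Inflation and multiplicity correction of p-values
#'
#' Applies the multiplicative inflation-factor correction (only when
#' lambda > 1; deflation is never applied, as shrinking p-values would be
#' anti-conservative) followed by Bonferroni correction over the number of
#' units tested in the arm, both capped at 1. A unit is called significant
#' when the fully corrected p-value is at most 0.05.
#'
#' @param p_raw Raw p-values in (0, 1].
#' @param lambda Inflation factor (> 0).
#' @param n_tests Number of units tested in the arm (>= 1).
#' @return A data.frame with columns `p_lambda` and `p_final`.
#' @export
correct_p <- function(p_raw, lambda, n_tests) {
  stopifnot(lambda > 0, n_tests >= 1)
  if (any(p_raw <= 0) || any(p_raw > 1)) stop("p_raw must lie in (0, 1]")
  p_lambda <- pmin(1, p_raw * max(lambda, 1))
  data.frame(p_lambda = p_lambda,
             p_final = pmin(1, p_lambda * n_tests))
}

#' Attach corrected p-values to a burden result
#'
#' Estimates lambda from the result's raw p-values (or uses a supplied
#' value) and adds `p_lambda`, `p_final` and a `significant` call at the
#' 0.05 threshold (inclusive).
#'
#' @param result A `BurdenResult` data.frame.
#' @param lambda Optional fixed inflation factor; when `NULL` it is
#'   estimated from `result$p_raw` via [estimate_lambda()].
#' @param alpha Significance threshold on the corrected p (default 0.05).
#' @return The result with columns `lambda`, `p_lambda`, `p_final`,
#'   `significant` appended.
#' @export
apply_corrections <- function(result, lambda = NULL, alpha = 0.05) {
  if (nrow(result) == 0) {
    result$lambda <- numeric()
    result$p_lambda <- numeric()
    result$p_final <- numeric()
    result$significant <- logical()
    return(result)
  }
  if (is.null(lambda)) {
    lambda <- suppressWarnings(estimate_lambda(result$p_raw)$lambda)
  }
  corr <- correct_p(result$p_raw, lambda, result$n_tests[1])
  result$lambda <- lambda
  result$p_lambda <- corr$p_lambda
  result$p_final <- corr$p_final
  result$significant <- result$p_final <= alpha
  result
}
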