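# The three two-sample tests and the correlation / fit kernels used by the
# SNV and CNV screens. Welch t and Mann-Whitney delegate to the stats
# implementations the field uses (t.test, wilcox.test); the Brown-Mood median
# test is implemented here as the 2x2 Pearson chi-square on the pooled-median
# dichotomy.

new_test_result <- function(statistic, p, method, n1, n2, df = NA_real_,
                            degenerate = FALSE) {
  structure(list(statistic = unname(statistic), p = unname(p), method = method,
                 n1 = n1, n2 = n2, df = unname(df), degenerate = degenerate),
            class = "drs_test")
}

#' @export
print.drs_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)%s\n",
              x$method, x$statistic, x$p, x$n1, x$n2,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Two-sample Welch t-test
#'
#' Location test not assuming equal variances, with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param x,y Numeric vectors, each of length >= 2; at least one group must
#'   have nonzero variance.
#' @return A `drs_test` with fields `statistic`, `p`, `method`, `n1`, `n2`,
#'   `df`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("Welch t-test needs at least 2 observations per group")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate comparison: both groups have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  new_test_result(ht$statistic, ht$p.value, "welch_t",
                  length(x), length(y), df = ht$parameter)
}

#' Two-sample Mann-Whitney-Wilcoxon test
#'
#' Rank-sum location test. The p-value is exact (equivalent to full
#' enumeration of group assignments) when both groups have fewer than 50
#' observations and there are no ties; otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A `drs_test`; `statistic` is the Mann-Whitney U for group `x`.
#' @export
mann_whitney_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("Mann-Whitney test needs at least 2 observations per group")
  ht <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  new_test_result(ht$statistic, ht$p.value, "mann_whitney",
                  length(x), length(y))
}

#' Two-sample Brown-Mood median test
#'
#' Dichotomizes the pooled values at the common median (strictly greater
#' than the median vs less-than-or-equal, the tie convention fixed here) and
#' tests the resulting 2x2 table with the Pearson chi-square statistic on 1
#' degree of freedom (no continuity correction by default). When the
#' dichotomy is degenerate (one margin empty, e.g. all pooled values equal),
#' the comparison carries no information and `p = 1` is returned with
#' `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param yates Apply the Yates continuity correction (default `FALSE`).
#' @return A `drs_test`; `statistic` is the chi-square value.
#' @export
mood_median_test <- function(x, y, yates = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("median test needs at least 2 observations per group")
  pooled <- c(x, y)
  m <- stats::median(pooled)
  a <- sum(x > m); b <- sum(x <= m)
  c_ <- sum(y > m); d <- sum(y <= m)
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0))
    return(new_test_result(0, 1, "mood_median", length(x), length(y),
                           df = 1, degenerate = TRUE))
  delta <- abs(a * d - b * c_)
  if (yates) delta <- max(0, delta - n / 2)
  chi2 <- n * delta^2 / prod(margins)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  new_test_result(chi2, p, "mood_median", length(x), length(y), df = 1)
}

#' Correlation coefficient
#'
#' Pearson product-moment, Spearman rank, or Kendall tau-b (tie-adjusted)
#' correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @param method `"pearson"`, `"spearman"`, or `"kendall"`.
#' @return Scalar coefficient in \[-1, 1\].
#' @export
correlation <- function(x, y, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant vector: correlation undefined")
  stats::cor(x, y, method = method)
}

#' Ordinary and robust simple linear fits
#'
#' `linear_fit()` is ordinary least squares; `huber_fit()` is the Huber
#' M-estimator (tuning constant 1.345) computed by iteratively reweighted
#' least squares via [MASS::rlm()] with coefficient tolerance 1e-8 and at
#' most 50 iterations. An exact fit (zero residual scale) is accepted as
#' converged.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` non-constant.
#' @return A list of class `drs_fit` with `slope`, `intercept`, `method`.
#' @export
linear_fit <- function(x, y) {
  check_fit_input(x, y)
  co <- stats::coef(stats::lm(y ~ x))
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 method = "lm"), class = "drs_fit")
}

#' @rdname linear_fit
#' @export
huber_fit <- function(x, y) {
  check_fit_input(x, y)
  fit <- suppressWarnings(
    MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
              acc = 1e-8, maxit = 50))
  exact <- max(abs(stats::residuals(fit))) <
    1e-8 * max(1, max(abs(y)))
  if (!fit$converged && !exact)
    stop(sprintf(
      "Huber IRLS did not converge in 50 iterations (last slope %.6g, intercept %.6g)",
      stats::coef(fit)[2L], stats::coef(fit)[1L]))
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 method = "rlm"), class = "drs_fit")
}

check_fit_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("fit needs at least 3 points")
  if (stats::var(x) == 0) stop("constant x: slope undefined")
  invisible(TRUE)
}

#' @export
print.drs_fit <- function(x, ...) {
  cat(sprintf("<%s fit> slope = %.4g, intercept = %.4g\n",
              x$method, x$slope, x$intercept))
  invisible(x)
}
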