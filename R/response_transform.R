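# Power transforms and normality assessment for drug-response measures.
#
# The screening tests downstream (notably the Welch t-test) work best on
# near-normal data, so each (panel, measure) pool is transformed once:
# nonnegative measures get a Box-Cox profile-likelihood lambda and a
# rule-based choice among identity / log / Box-Cox; measures with negative
# values (LFC) get a Yeo-Johnson transform at the MLE lambda. Transformed
# pools are mean-centered so downstream group means are shifts around 0.

#' Box-Cox power transform
#'
#' \eqn{y = (x^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0}, \eqn{\log x}
#' for \eqn{\lambda = 0}; continuous in \eqn{\lambda} at 0.
#'
#' @param x Positive numeric vector (zeros allowed only when `lambda > 0`).
#' @param lambda Power parameter.
#' @return Transformed vector.
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(x < 0)) stop("Box-Cox transform requires nonnegative data")
  if (any(x == 0) && lambda <= 0)
    stop("Box-Cox transform undefined at x = 0 with lambda <= 0")
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Yeo-Johnson power transform
#'
#' The four-branch power transform defined for all reals:
#' \eqn{((x+1)^\lambda - 1)/\lambda} for \eqn{x \ge 0, \lambda \ne 0};
#' \eqn{\log(x+1)} for \eqn{x \ge 0, \lambda = 0};
#' \eqn{-((1-x)^{2-\lambda} - 1)/(2-\lambda)} for \eqn{x < 0, \lambda \ne 2};
#' \eqn{-\log(1-x)} for \eqn{x < 0, \lambda = 2}.
#' Strictly increasing in `x` for every `lambda`.
#'
#' @param x Numeric vector.
#' @param lambda Power parameter.
#' @return Transformed vector.
#' @export
yeojohnson_transform <- function(x, lambda) {
  y <- numeric(length(x))
  pos <- x >= 0
  if (lambda == 0) {
    y[pos] <- log(x[pos] + 1)
  } else {
    y[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  }
  if (lambda == 2) {
    y[!pos] <- -log(1 - x[!pos])
  } else {
    y[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  }
  y
}

# Profile log-likelihood of lambda under a normal model for the transformed
# data, including the log-Jacobian of the transform.
power_loglik <- function(x, lambda, family) {
  n <- length(x)
  y <- if (family == "boxcox") boxcox_transform(x, lambda)
       else yeojohnson_transform(x, lambda)
  v <- stats::var(y) * (n - 1) / n
  if (!is.finite(v) || v <= 0) return(-Inf)
  jac <- if (family == "boxcox") (lambda - 1) * sum(log(x))
         else (lambda - 1) * sum(sign(x) * log(abs(x) + 1))
  -n / 2 * log(v) + jac
}

#' Estimate the power-transform parameter by profile likelihood
#'
#' Maximizes the normal-model profile log-likelihood (with Jacobian) over
#' \eqn{\lambda \in [-2, 2]} on a 0.01 grid, then refines by golden-section
#' search around the grid optimum. Deterministic for fixed input.
#'
#' @param x Numeric vector, `length(x) >= 20`, non-constant; strictly
#'   positive for `family = "boxcox"`.
#' @param family `"boxcox"` or `"yeojohnson"`.
#' @return Estimated lambda (scalar).
#' @export
estimate_power_lambda <- function(x, family = c("boxcox", "yeojohnson")) {
  family <- match.arg(family)
  x <- x[is.finite(x)]
  if (length(x) < 20L)
    stop("need at least 20 observations to estimate lambda")
  if (stats::var(x) == 0)
    stop("constant input: power-transform likelihood undefined")
  if (family == "boxcox" && any(x <= 0))
    stop("Box-Cox lambda estimation requires strictly positive data")
  grid <- seq(-2, 2, by = 0.01)
  ll <- vapply(grid, function(l) power_loglik(x, l, family), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  # golden-section refinement inside the bracketing grid cell
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- power_loglik(x, c1, family); fd <- power_loglik(x, d1, family)
  for (k in seq_len(60L)) {
    if (b - a < 1e-6) break
    if (fc > fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- power_loglik(x, c1, family)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- power_loglik(x, d1, family)
    }
  }
  (a + b) / 2
}

#' One-sample Kolmogorov-Smirnov normality assessment
#'
#' Compares the empirical CDF of `x` with the normal distribution fitted by
#' moments (`Normal(mean(x), sd(x))`), reporting the sup-distance `KS.D` and
#' the asymptotic Kolmogorov p-value `KS.p`. Because mean and sd are
#' estimated from the same data, the p-value is anti-conservative (the
#' Lilliefors effect); it is used here as a descriptive index of normality,
#' not a calibrated test.
#'
#' @param x Numeric vector, `length(x) >= 8`, non-constant.
#' @return List with `ks_d`, `ks_p`, `n`, `mean`, `sd`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8L) stop("need at least 8 observations for the KS assessment")
  s <- stats::sd(x)
  if (s == 0) stop("constant input: normality assessment undefined")
  kt <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = s, exact = FALSE))
  list(ks_d = unname(kt$statistic), ks_p = kt$p.value,
       n = length(x), mean = mean(x), sd = s)
}

#' Select and apply the response transform for one measure pool
#'
#' Implements the transformation-selection rule applied per (panel, measure)
#' pool:
#' * nonnegative measures (`AUC`, `EC50`, `IC50`): estimate the Box-Cox
#'   \eqn{\hat\lambda}; use the identity when \eqn{|\hat\lambda - 1| \le 0.25}
#'   ("lambda close to 1"), the log when \eqn{|\hat\lambda| \le 0.25}
#'   ("lambda close to 0"), and Box-Cox(\eqn{\hat\lambda}) otherwise;
#' * measures containing negative values (`LFC`): Yeo-Johnson at the MLE
#'   \eqn{\hat\lambda}.
#'
#' The transformed pool is then mean-centered; the subtracted center is
#' recorded so the same transform can be replayed on new values.
#'
#' @param measure One of [response_measures()].
#' @param values Numeric vector of raw responses pooled across the panel's
#'   drugs for this measure (at least 20 values).
#' @return List with `spec` (a `transform_spec`: `measure`, `family`,
#'   `lambda`, `center`) and `values` (transformed, centered).
#' @export
select_and_apply_transform <- function(measure, values) {
  measure <- match.arg(measure, MEASURE_LEVELS)
  values <- values[is.finite(values)]
  if (length(values) < 20L)
    stop("fewer than 20 values for measure ", measure,
         ": too few to select a transform; analyze on the raw scale instead")
  if (measure %in% c("AUC", "EC50", "IC50")) {
    if (any(values < 0))
      stop("negative values in nonnegative measure ", measure)
    lambda_hat <- estimate_power_lambda(values, "boxcox")
    if (abs(lambda_hat - 1) <= 0.25) {
      family <- "identity"; lambda <- NA_real_; y <- values
    } else if (abs(lambda_hat) <= 0.25) {
      family <- "log"; lambda <- NA_real_; y <- log(values)
    } else {
      family <- "boxcox"; lambda <- lambda_hat
      y <- boxcox_transform(values, lambda)
    }
  } else {
    lambda <- estimate_power_lambda(values, "yeojohnson")
    family <- "yeojohnson"
    y <- yeojohnson_transform(values, lambda)
  }
  center <- mean(y)
  spec <- structure(list(measure = measure, family = family, lambda = lambda,
                         center = center),
                    class = "transform_spec")
  list(spec = spec, values = y - center)
}

#' Replay a recorded transform on new values
#'
#' @param spec A `transform_spec` from [select_and_apply_transform()] (or
#'   [identity_transform_spec()]).
#' @param values Numeric vector on the raw scale.
#' @return Transformed, centered values.
#' @export
apply_transform <- function(spec, values) {
  stopifnot(inherits(spec, "transform_spec"))
  y <- switch(spec$family,
    identity = values,
    log = log(values),
    boxcox = boxcox_transform(values, spec$lambda),
    yeojohnson = yeojohnson_transform(values, spec$lambda),
    stop("unknown transform family: ", spec$family))
  y - spec$center
}

#' Identity transform (raw-scale analysis)
#'
#' Convenience spec for running the screens on raw values.
#'
#' @param measure One of [response_measures()].
#' @return A `transform_spec` with family `"identity"` and center 0.
#' @export
identity_transform_spec <- function(measure) {
  structure(list(measure = match.arg(measure, MEASURE_LEVELS),
                 family = "identity", lambda = NA_real_, center = 0),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform_spec> %s: %s%s, center %.4g\n", x$measure, x$family,
              if (is.na(x$lambda)) "" else sprintf("(lambda = %.3f)", x$lambda),
              x$center))
  invisible(x)
}

#' Correlation between two response measures of one drug
#'
#' Pairs samples having both measures for the drug and reports Pearson's
#' correlation, Spearman's rho, and Kendall's tau-b. EC50 (and IC50) values
#' are log-transformed before pairing, since they live on a multiplicative
#' scale.
#'
#' @param resp A response table.
#' @param drug Drug name.
#' @param m1,m2 Measure labels to compare.
#' @return Named numeric vector `c(p_cor, s_rho, k_tau)`.
#' @export
measure_pair_correlation <- function(resp, drug, m1, m2) {
  pick <- function(m) {
    sub <- resp[resp$drug == drug & resp$measure == m, c("sample", "value")]
    v <- sub$value
    if (m %in% c("EC50", "IC50")) v <- log(v)
    stats::setNames(v, sub$sample)
  }
  v1 <- pick(m1); v2 <- pick(m2)
  common <- intersect(names(v1), names(v2))
  if (length(common) < 3L)
    stop("fewer than 3 samples with both ", m1, " and ", m2,
         " for drug '", drug, "'")
  x <- v1[common]; y <- v2[common]
  c(p_cor = stats::cor(x, y, method = "pearson"),
    s_rho = stats::cor(x, y, method = "spearman"),
    k_tau = stats::cor(x, y, method = "kendall"))
}
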