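test_that("Box-Cox transform matches its closed forms", {
  expect_equal(boxcox_transform(c(1, 2, 4), 1), c(0, 1, 3))
  expect_equal(boxcox_transform(c(1, exp(1), exp(2)), 0), c(0, 1, 2))
  expect_equal(boxcox_transform(3, 2), 4)
  expect_error(boxcox_transform(c(1, 0), 0), "lambda <= 0")
  expect_error(boxcox_transform(-1, 1), "nonnegative")
})

test_that("Box-Cox at lambda = 0 is the limit of lambda -> 0", {
  x <- seq(0.5, 2, length.out = 30)
  expect_equal(boxcox_transform(x, 1e-7), log(x), tolerance = 1e-6)
})

test_that("Yeo-Johnson transform matches its four branches", {
  expect_equal(yeojohnson_transform(-2, 1), -2)
  expect_equal(yeojohnson_transform(exp(1) - 1, 0), 1)
  expect_equal(yeojohnson_transform(-1, 2), -log(2))
  # positive branch, lambda != 0
  expect_equal(yeojohnson_transform(3, 2), ((3 + 1)^2 - 1) / 2)
})

test_that("both transforms preserve value order for every lambda", {
  set.seed(7)
  x_pos <- sort(rlnorm(25))
  x_any <- sort(rnorm(25))
  for (lambda in c(-2, -0.6, 0, 0.5, 1, 1.7, 2)) {
    if (lambda > 0 || all(x_pos > 0))
      expect_equal(order(boxcox_transform(x_pos, lambda)), seq_along(x_pos))
    expect_equal(order(yeojohnson_transform(x_any, lambda)),
                 seq_along(x_any))
  }
})

test_that("lambda estimation recovers the generating power", {
  set.seed(11)
  x_norm <- abs(rnorm(500, 1.0, 0.1))
  expect_gt(estimate_power_lambda(x_norm, "boxcox"), 0.5)
  expect_lt(estimate_power_lambda(x_norm, "boxcox"), 1.5)

  set.seed(12)
  x_lnorm <- exp(rnorm(1000))
  lam <- estimate_power_lambda(x_lnorm, "boxcox")
  expect_gt(lam, -0.15)
  expect_lt(lam, 0.15)

  # data that are Box-Cox(0.5)-normal: invert the transform of normal draws
  set.seed(13)
  z <- rnorm(800, 2, 0.3)
  x_bc <- (0.5 * z + 1)^2   # inverse of (x^0.5 - 1) / 0.5
  lam2 <- estimate_power_lambda(x_bc, "boxcox")
  expect_gt(lam2, 0.3)
  expect_lt(lam2, 0.7)

  expect_error(estimate_power_lambda(rep(1, 30), "boxcox"), "constant")
  expect_error(estimate_power_lambda(rlnorm(10), "boxcox"), "at least 20")
})

test_that("lambda estimate agrees with the MASS profile-likelihood oracle", {
  set.seed(21)
  x <- exp(rnorm(400, 0, 0.8)) + 0.2
  lam <- estimate_power_lambda(x, "boxcox")
  prof <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(lam - prof$x[which.max(prof$y)]), 0.02)
})

test_that("KS normality report matches a direct CDF-distance computation", {
  x <- rep(c(-1, 1), 50)
  rep_ <- ks_normality(x)
  expect_equal(rep_$ks_d, ks_d_direct(x, mean(x), sd(x)), tolerance = 1e-12)
  expect_lt(rep_$ks_p, 0.05)

  set.seed(31)
  z <- rnorm(100)
  expect_gt(ks_normality(z)$ks_p, 0.05)

  set.seed(32)
  u <- runif(1000)
  expect_lt(ks_normality(u)$ks_p, 0.05)

  expect_error(ks_normality(rep(2, 20)), "constant")
  expect_error(ks_normality(rnorm(5)), "at least 8")
})

test_that("the transform-selection rule maps pool shapes to families", {
  set.seed(41)
  auc_pool <- abs(rnorm(400, 1.0, 0.15))
  res <- select_and_apply_transform("AUC", auc_pool)
  expect_equal(res$spec$family, "identity")
  expect_equal(mean(res$values), 0, tolerance = 1e-9)

  set.seed(42)
  ec50_pool <- exp(rnorm(400, 0.5, 1))
  res2 <- select_and_apply_transform("EC50", ec50_pool)
  expect_equal(res2$spec$family, "log")
  expect_equal(mean(res2$values), 0, tolerance = 1e-9)
  expect_equal(res2$values, log(ec50_pool) - mean(log(ec50_pool)))

  set.seed(43)
  lfc_pool <- c(rnorm(199), -3.2)
  res3 <- select_and_apply_transform("LFC", lfc_pool)
  expect_equal(res3$spec$family, "yeojohnson")
  expect_equal(mean(res3$values), 0, tolerance = 1e-9)

  expect_error(select_and_apply_transform("AUC", runif(10)),
               "raw scale")
  expect_error(select_and_apply_transform("AUC", c(-1, runif(30))),
               "negative values")
})

test_that("a recorded transform replays identically on the fitting data", {
  set.seed(44)
  pool <- exp(rnorm(300))
  res <- select_and_apply_transform("EC50", pool)
  expect_equal(apply_transform(res$spec, pool), res$values)
})

test_that("measure-pair correlation reports all three coefficients", {
  resp <- as_response_table(data.frame(
    sample = rep(sprintf("s%02d", 1:20), 2),
    drug = "dA",
    measure = rep(c("AUC", "LFC"), each = 20),
    value = c(seq(0.1, 2, 0.1), 2 * seq(0.1, 2, 0.1))))
  r <- measure_pair_correlation(resp, "dA", "AUC", "LFC")
  expect_equal(unname(r), c(1, 1, 1))

  # monotone but nonlinear: rank coefficients stay 1, Pearson drops
  resp2 <- as_response_table(data.frame(
    sample = rep(sprintf("s%02d", 1:10), 2),
    drug = "dA",
    measure = rep(c("AUC", "LFC"), each = 10),
    value = c(1:10, (1:10)^3)))
  r2 <- measure_pair_correlation(resp2, "dA", "AUC", "LFC")
  expect_equal(unname(r2[c("s_rho", "k_tau")]), c(1, 1))
  expect_lt(r2[["p_cor"]], 1)

  # independent measures stay near zero
  set.seed(51)
  resp3 <- as_response_table(data.frame(
    sample = rep(sprintf("s%03d", 1:200), 2),
    drug = "dA",
    measure = rep(c("AUC", "LFC"), each = 200),
    value = c(abs(rnorm(200, 1, 0.2)), rnorm(200))))
  r3 <- measure_pair_correlation(resp3, "dA", "AUC", "LFC")
  expect_true(all(abs(r3) < 0.15))

  expect_error(measure_pair_correlation(resp, "missing-drug", "AUC", "LFC"),
               "fewer than 3")
})
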