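test_that("copy-number binning follows the two rounding modes", {
  expect_equal(bin_cnv(1.4, "nearest"), 1L)
  expect_equal(bin_cnv(3.5, "nearest"), 4L)  # half away from zero
  expect_equal(bin_cnv(1.2, "ceiling"), 2L)
  expect_equal(bin_cnv(c(0.4, 2.5), "nearest"), c(0L, 3L))
  # modes agree on exact integers
  for (k in 0:5) {
    expect_equal(bin_cnv(k, "nearest"), k)
    expect_equal(bin_cnv(k, "ceiling"), k)
  }
  expect_error(bin_cnv(-0.1), "nonnegative")
})

test_that("max-driver-CNV groups partition samples and collapse at 4+", {
  cn <- as_copynumber_matrix(matrix(
    c(1.1, 2.7, 5.2,
      1.0, 0.9, 1.1,
      0.2, 0.3, 0.1), nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C"))))
  g <- max_driver_cnv_groups(cn, c("A", "B", "C"))
  expect_equal(as.character(g$bin), c("4+", "1", "0"))
  expect_equal(nrow(g), 3L)

  # invariant to driver list order
  g2 <- max_driver_cnv_groups(cn, c("C", "B", "A"))
  expect_equal(g, g2)

  expect_error(max_driver_cnv_groups(cn, "ZZZ"), "none of the driver genes")
})

test_that("all assignments for a sizable cohort form a partition", {
  set.seed(8)
  cn <- as_copynumber_matrix(matrix(
    abs(rnorm(10 * 3, 1, 0.15)), nrow = 10,
    dimnames = list(sprintf("s%02d", 1:10), c("A", "B", "C"))))
  g <- max_driver_cnv_groups(cn, c("A", "B"))
  expect_equal(sort(g$sample), sort(rownames(cn)))
  expect_false(any(is.na(g$bin)))
})

test_that("response coupled to CNV yields increasing per-bin means", {
  set.seed(9)
  n <- 400
  samples <- sprintf("s%03d", 1:n)
  # spread CNVs across bins 1..5 so every group is populated
  cnv_vals <- runif(n, 0.6, 5.4)
  cn <- as_copynumber_matrix(matrix(cnv_vals, ncol = 1,
                                    dimnames = list(samples, "A")))
  resp <- as_response_table(data.frame(
    sample = samples, drug = "dA", measure = "LFC",
    value = 0.8 * cnv_vals + rnorm(n, 0, 0.2)))
  g <- max_driver_cnv_groups(cn, "A")
  out <- cnv_group_response_summary(g, resp, "dA", "LFC")
  means <- out$summary$mean[out$summary$bin %in% c("1", "2", "3", "4+")]
  expect_true(all(diff(means) > 0))
  expect_gt(out$trend_tau, 0.5)
})

test_that("a null cohort shows no bin trend and single-value bins no quartiles", {
  set.seed(10)
  n <- 300
  samples <- sprintf("s%03d", 1:n)
  cn <- as_copynumber_matrix(matrix(runif(n, 0.6, 5.4), ncol = 1,
                                    dimnames = list(samples, "A")))
  resp <- as_response_table(data.frame(
    sample = samples, drug = "dA", measure = "LFC", value = rnorm(n)))
  out <- cnv_group_response_summary(max_driver_cnv_groups(cn, "A"),
                                    resp, "dA", "LFC")
  expect_lt(abs(out$trend_tau), 0.1)

  cn1 <- as_copynumber_matrix(matrix(c(1.0, 1.1, 2.1), ncol = 1,
                                     dimnames = list(paste0("s", 1:3), "A")))
  resp1 <- as_response_table(data.frame(
    sample = paste0("s", 1:3), drug = "dA", measure = "AUC",
    value = c(0.9, 1.0, 1.2)))
  out1 <- cnv_group_response_summary(max_driver_cnv_groups(cn1, "A"),
                                     resp1, "dA", "AUC")
  b2 <- out1$summary[out1$summary$bin == "2", ]
  expect_equal(b2$n, 1L)
  expect_true(is.na(b2$q25))
})

test_that("continuous CNV association recovers exact and planted relations", {
  samples <- sprintf("s%03d", 1:50)
  cnv_vals <- seq(0.5, 3, length.out = 50)
  cn <- as_copynumber_matrix(matrix(cnv_vals, ncol = 1,
                                    dimnames = list(samples, "A")))
  resp <- as_response_table(data.frame(
    sample = samples, drug = "dA", measure = "LFC",
    value = 2 + 3 * cnv_vals))
  assoc <- cnv_gene_association(cn, resp, "A", "dA", "LFC")
  expect_equal(assoc$p_cor, 1)
  expect_equal(assoc$lm_slope, 3, tolerance = 1e-8)

  # independent CNV and response: small coefficients at n = 300
  set.seed(12)
  n <- 300
  samples <- sprintf("s%03d", 1:n)
  cn2 <- as_copynumber_matrix(matrix(abs(rnorm(n, 1, 0.15)), ncol = 1,
                                     dimnames = list(samples, "A")))
  resp2 <- as_response_table(data.frame(
    sample = samples, drug = "dA", measure = "LFC", value = rnorm(n)))
  a2 <- cnv_gene_association(cn2, resp2, "A", "dA", "LFC")
  expect_lt(abs(a2$p_cor), 0.15)

  # constant CNV: not evaluable, no error
  cn3 <- as_copynumber_matrix(matrix(rep(1, n), ncol = 1,
                                     dimnames = list(samples, "A")))
  a3 <- cnv_gene_association(cn3, resp2, "A", "dA", "LFC")
  expect_false(a3$evaluable)
})

test_that("rank coefficients are invariant under monotone response transforms", {
  set.seed(13)
  n <- 60
  samples <- sprintf("s%03d", 1:n)
  cnv_vals <- abs(rnorm(n, 1, 0.3))
  cn <- as_copynumber_matrix(matrix(cnv_vals, ncol = 1,
                                    dimnames = list(samples, "A")))
  v <- cnv_vals + rnorm(n, 0, 0.5)
  r1 <- as_response_table(data.frame(sample = samples, drug = "d",
                                     measure = "LFC", value = v))
  r2 <- as_response_table(data.frame(sample = samples, drug = "d",
                                     measure = "LFC", value = exp(v)))
  a1 <- cnv_gene_association(cn, r1, "A", "d", "LFC")
  a2 <- cnv_gene_association(cn, r2, "A", "d", "LFC")
  expect_equal(a1$s_rho, a2$s_rho, tolerance = 1e-12)
  expect_equal(a1$k_tau, a2$k_tau, tolerance = 1e-12)
})
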