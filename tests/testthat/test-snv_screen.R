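make_mut <- function(calls, samples, genes) {
  as_mutation_matrix(matrix(calls, nrow = length(samples), byrow = TRUE,
                            dimnames = list(samples, genes)))
}

test_that("driver-set partition covers every sample exactly once", {
  m <- make_mut(c(1, 0,
                  0, 0,
                  0, 0,
                  0, 0), paste0("s", 1:4), c("A", "B"))
  part <- partition_by_driver_set(m, c("A", "B"))
  expect_equal(length(part$mutated), 1L)
  expect_equal(length(part$unmutated), 3L)
  expect_setequal(c(part$mutated, part$unmutated), paste0("s", 1:4))

  # membership is idempotent: mutations in several drivers count once
  m2 <- make_mut(c(1, 1, 1,
                   0, 0, 0), c("s1", "s2"), c("A", "B", "C"))
  part2 <- partition_by_driver_set(m2, c("A", "B", "C"))
  expect_equal(part2$mutated, "s1")

  expect_warning(partition_by_driver_set(m, c("A", "ZZZ")), "ZZZ")
  expect_error(partition_by_driver_set(m, "ZZZ"), "none of the driver genes")

  # all-zero matrix: mutated group empty
  m0 <- make_mut(rep(0, 4), c("s1", "s2"), c("A", "B"))
  expect_equal(length(partition_by_driver_set(m0, "A")$mutated), 0L)
})

test_that("group comparison reports sizes, means, and three p-values", {
  samples <- sprintf("s%03d", 1:200)
  part <- list(mutated = samples[1:100], unmutated = samples[101:200])
  set.seed(5)
  vals <- c(rnorm(100, 1, 1), rnorm(100, 0, 1))  # 1 pooled-SD shift
  resp <- as_response_table(data.frame(sample = samples, drug = "dA",
                                       measure = "LFC", value = vals))
  comp <- compare_groups(resp, part, "dA", "LFC")
  expect_true(comp$evaluable)
  expect_equal(comp$n_mut, 100L)
  expect_true(all(c(comp$p_t, comp$p_w, comp$p_m) < 0.01))

  # copied groups: no shift, all p near 1
  resp2 <- as_response_table(data.frame(
    sample = samples, drug = "dA", measure = "LFC",
    value = rep(rnorm(100), 2)))
  comp2 <- compare_groups(resp2, part, "dA", "LFC")
  expect_equal(comp2$mean_mut - comp2$mean_unmut, 0)
  expect_true(all(c(comp2$p_t, comp2$p_w, comp2$p_m) > 0.99))
})

test_that("a single mutated sample makes the comparison not-evaluable", {
  samples <- paste0("s", 1:10)
  part <- list(mutated = samples[1], unmutated = samples[2:10])
  resp <- as_response_table(data.frame(sample = samples, drug = "dA",
                                       measure = "AUC", value = runif(10)))
  comp <- compare_groups(resp, part, "dA", "AUC")
  expect_false(comp$evaluable)
  expect_true(is.na(comp$p_t))
  expect_equal(comp$n_mut, 1L)
})

test_that("consensus rules reproduce the worked-example verdicts", {
  strict <- screening_rule("strict")
  relaxed <- screening_rule("relaxed")
  # all three < 0.05
  expect_true(passes_rule(0.031, 0.032, 0.019, strict))
  # one < 0.01 carries the call alone
  expect_true(passes_rule(0.085, 0.049, 0.009, strict))
  # two < 0.05 passes only the relaxed rule
  expect_false(passes_rule(0.011, 0.037, 0.157, strict))
  expect_true(passes_rule(0.011, 0.037, 0.157, relaxed))
  # thresholds are strict inequalities
  expect_false(passes_rule(0.05, 0.05, 0.05, strict))
  expect_false(passes_rule(0.05, 0.05, 0.05, relaxed))
})

test_that("screening is monotone: lowering a p-value never removes a call", {
  set.seed(6)
  for (rule in list(screening_rule("strict"), screening_rule("relaxed"))) {
    p <- matrix(runif(300), ncol = 3)
    base <- passes_rule(p[, 1], p[, 2], p[, 3], rule)
    shrink <- p * matrix(runif(300, 0.1, 1), ncol = 3)
    after <- passes_rule(shrink[, 1], shrink[, 2], shrink[, 3], rule)
    expect_true(all(after[base]))
  }
})

test_that("strict implies relaxed for triples with min p >= 0.01", {
  # a triple below 0.01 in one test only can pass strict but not relaxed,
  # e.g. (0.005, 0.2, 0.3); above that floor the implication is exact
  expect_true(passes_rule(0.005, 0.2, 0.3, screening_rule("strict")))
  expect_false(passes_rule(0.005, 0.2, 0.3, screening_rule("relaxed")))
  grid <- seq(0.011, 0.2, by = 0.003)
  trip <- expand.grid(p_t = grid, p_w = grid, p_m = grid)
  s <- passes_rule(trip$p_t, trip$p_w, trip$p_m, screening_rule("strict"))
  r <- passes_rule(trip$p_t, trip$p_w, trip$p_m, screening_rule("relaxed"))
  expect_true(all(r[s]))
})

test_that("biomarker calls aggregate passing drugs per gene with categories", {
  comp <- rbind(
    data.frame(target = "BRAF", drug = paste0("d", 1:4), measure = "AUC",
               n_mut = 50, n_unmut = 50, mean_mut = 0, mean_unmut = 1,
               p_t = 0.001, p_w = 0.001, p_m = 0.001, evaluable = TRUE),
    data.frame(target = "NRAS", drug = c("d1", "d2"), measure = "AUC",
               n_mut = 30, n_unmut = 70, mean_mut = 0, mean_unmut = 1,
               p_t = c(0.02, 0.5), p_w = c(0.03, 0.5), p_m = c(0.04, 0.5),
               evaluable = TRUE),
    data.frame(target = "KIT", drug = "d1", measure = "AUC",
               n_mut = 2, n_unmut = 98, mean_mut = NA, mean_unmut = NA,
               p_t = NA, p_w = NA, p_m = NA, evaluable = FALSE),
    data.frame(target = "DRIVER_SET", drug = "d1", measure = "AUC",
               n_mut = 60, n_unmut = 40, mean_mut = 0, mean_unmut = 1,
               p_t = 1e-5, p_w = 1e-5, p_m = 1e-5, evaluable = TRUE))
  calls <- call_biomarkers(comp, screening_rule("strict"))
  expect_equal(calls$gene, c("BRAF", "NRAS"))  # driver set never called
  expect_equal(calls$category, c("3+", "1"))
  expect_equal(calls$n_affected_drugs, c(4L, 1L))

  expect_equal(categorize_by_drug_count(1), "1")
  expect_equal(categorize_by_drug_count(2), "2")
  expect_equal(categorize_by_drug_count(4), "3+")
})

test_that("evidence tiers follow the significance ladder; BH flag tightens calls", {
  expect_equal(evidence_tier(c(0.005, 0.02, 0.07, 0.5, NA),
                             c(0.5, 0.5, 0.5, 0.5, NA),
                             c(0.5, 0.5, 0.5, 0.5, NA)),
               c("strong", "moderate", "weak", "none", "none"))
  # 20 comparisons, one marginal signal: BH adjustment removes the call
  comp <- data.frame(target = paste0("g", 1:20), drug = "d1",
                     measure = "AUC", n_mut = 20, n_unmut = 80,
                     mean_mut = 0, mean_unmut = 1,
                     p_t = c(0.04, seq(0.2, 0.96, length.out = 19)),
                     p_w = c(0.03, seq(0.2, 0.96, length.out = 19)),
                     p_m = c(0.04, seq(0.2, 0.96, length.out = 19)),
                     evaluable = TRUE)
  expect_equal(call_biomarkers(comp)$gene, "g1")
  expect_equal(nrow(call_biomarkers(comp, adjust = "BH")), 0L)
})

test_that("cross-cancer span counts distinct panels per gene", {
  call_row <- function(gene) data.frame(
    gene = gene, measure = "AUC", n_affected_drugs = 1L, category = "1",
    affected_drugs = "d", stringsAsFactors = FALSE)
  calls <- list(
    BRCA = rbind(call_row("SALL4"), call_row("TP53")),
    SKCM = call_row("SALL4"),
    CRC = rbind(call_row("SALL4"), call_row("SALL4")),  # twice in one panel
    GB = call_row("SALL4"))
  span <- cross_cancer_span(calls)
  expect_equal(span$gene[1L], "SALL4")
  expect_equal(span$n_cancers[1L], 4L)
  expect_equal(span$n_cancers[span$gene == "TP53"], 1L)
  expect_equal(nrow(cross_cancer_span(list())), 0L)
})
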