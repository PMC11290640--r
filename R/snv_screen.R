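# Mutation-defined group comparisons and the consensus biomarker-calling
# rule. Each (gene, drug, measure) comparison runs the three tests on the
# transformed responses of mutated vs unmutated samples; a gene-drug pair is
# called under the strict rule when all three p-values are below 0.05 or any
# one is below 0.01, and under the relaxed rule when at least two are below
# 0.05.

#' Partition samples by a driver gene set
#'
#' Samples carrying at least one SNV in any listed driver gene form the
#' mutated group; the rest form the unmutated group. Drivers absent from the
#' matrix are dropped with a warning.
#'
#' @param m A mutation matrix (samples x genes, 0/1).
#' @param drivers Character vector of driver gene symbols.
#' @return List with `mutated` and `unmutated` sample-id vectors; the two
#'   cover all samples exactly once.
#' @export
partition_by_driver_set <- function(m, drivers) {
  present <- intersect(drivers, colnames(m))
  missing <- setdiff(drivers, colnames(m))
  if (length(present) == 0L)
    stop("none of the driver genes are present in the mutation matrix")
  if (length(missing) > 0L)
    warning("driver gene(s) not in mutation matrix, dropped: ",
            paste(missing, collapse = ", "))
  any_mut <- rowSums(m[, present, drop = FALSE]) > 0
  list(mutated = rownames(m)[any_mut], unmutated = rownames(m)[!any_mut])
}

#' Partition samples by a single gene's mutation status
#'
#' @param m A mutation matrix.
#' @param gene Gene symbol (must be a column of `m`).
#' @return List with `mutated` and `unmutated` sample-id vectors.
#' @export
partition_by_gene <- function(m, gene) {
  if (!gene %in% colnames(m))
    stop("gene '", gene, "' not in mutation matrix")
  mut <- m[, gene] > 0
  list(mutated = rownames(m)[mut], unmutated = rownames(m)[!mut])
}

#' Compare drug response between mutated and unmutated groups
#'
#' Joins the partition with the response table for one (drug, measure),
#' applies the recorded transform, and runs the Welch t, Mann-Whitney, and
#' Brown-Mood median tests. Comparisons where either group has fewer than
#' `min_group` response values are marked not-evaluable (p-values `NA`)
#' rather than dropped, so screening reports can count them.
#'
#' @param resp A response table.
#' @param partition List with `mutated`/`unmutated` sample ids (from
#'   [partition_by_gene()] or [partition_by_driver_set()]).
#' @param drug Drug name.
#' @param measure Measure label.
#' @param transform A `transform_spec`; defaults to the identity (raw scale).
#' @param target Label recorded in the output (gene symbol or
#'   `"DRIVER_SET"`).
#' @param min_group Minimum per-group size for evaluability (default 2).
#' @return One-row `data.frame` with columns `target`, `drug`, `measure`,
#'   `n_mut`, `n_unmut`, `mean_mut`, `mean_unmut`, `p_t`, `p_w`, `p_m`,
#'   `evaluable`.
#' @export
compare_groups <- function(resp, partition, drug, measure,
                           transform = identity_transform_spec(measure),
                           target = "DRIVER_SET", min_group = 2L) {
  sub <- resp[resp$drug == drug & resp$measure == measure, ]
  vals <- stats::setNames(sub$value, sub$sample)
  x_raw <- vals[names(vals) %in% partition$mutated]
  y_raw <- vals[names(vals) %in% partition$unmutated]
  row <- data.frame(target = target, drug = drug, measure = measure,
                    n_mut = length(x_raw), n_unmut = length(y_raw),
                    mean_mut = NA_real_, mean_unmut = NA_real_,
                    p_t = NA_real_, p_w = NA_real_, p_m = NA_real_,
                    evaluable = FALSE, stringsAsFactors = FALSE)
  if (length(x_raw) < min_group || length(y_raw) < min_group) return(row)
  x <- apply_transform(transform, unname(x_raw))
  y <- apply_transform(transform, unname(y_raw))
  row$mean_mut <- mean(x)
  row$mean_unmut <- mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # no variation anywhere: no evidence of a shift
    row$p_t <- row$p_w <- row$p_m <- 1
    row$evaluable <- TRUE
    return(row)
  }
  row$p_t <- welch_t_test(x, y)$p
  row$p_w <- mann_whitney_test(x, y)$p
  row$p_m <- mood_median_test(x, y)$p
  row$evaluable <- TRUE
  row
}

#' Screen every driver gene of a panel against every drug
#'
#' Runs [compare_groups()] for each (driver gene, drug) pair of one measure,
#' using a transform fitted once on the pooled measure values.
#'
#' @param m Mutation matrix.
#' @param resp Response table.
#' @param panel A [cancer_panel()].
#' @param measure Measure label (must belong to the panel).
#' @param transform A `transform_spec` for this measure.
#' @param min_group Minimum per-group size (default 2).
#' @return `data.frame` of comparisons, one row per (gene, drug).
#' @export
screen_panel_genes <- function(m, resp, panel, measure,
                               transform = identity_transform_spec(measure),
                               min_group = 2L) {
  genes <- intersect(panel$driver_genes, colnames(m))
  rows <- list()
  for (gene in genes) {
    part <- partition_by_gene(m, gene)
    for (drug in panel$drugs) {
      rows[[length(rows) + 1L]] <-
        compare_groups(resp, part, drug, measure, transform,
                       target = gene, min_group = min_group)
    }
  }
  do.call(rbind, rows)
}

#' Consensus screening rules
#'
#' @param mode `"strict"` (all three p-values < 0.05, or any one < 0.01) or
#'   `"relaxed"` (at least two of the three < 0.05).
#' @param thresholds Significance ladder; the first two entries are the
#'   strong (0.01) and moderate (0.05) evidence thresholds used for calling,
#'   the third (0.1) is a weak-evidence annotation tier only.
#' @return List of class `screening_rule`.
#' @export
screening_rule <- function(mode = c("strict", "relaxed"),
                           thresholds = c(0.01, 0.05, 0.1)) {
  mode <- match.arg(mode)
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  structure(list(mode = mode, thresholds = thresholds),
            class = "screening_rule")
}

#' Does a p-value triple pass a screening rule?
#'
#' @param p_t,p_w,p_m The Welch t, Mann-Whitney, and median-test p-values
#'   (vectors are recycled elementwise).
#' @param rule A [screening_rule()].
#' @return Logical vector; `NA` p-values never pass.
#' @export
passes_rule <- function(p_t, p_w, p_m, rule = screening_rule("strict")) {
  strong <- rule$thresholds[1L]
  moderate <- rule$thresholds[2L]
  p <- cbind(p_t, p_w, p_m)
  ok <- stats::complete.cases(p)
  out <- logical(nrow(p))
  if (!any(ok)) return(out)
  q <- p[ok, , drop = FALSE]
  if (rule$mode == "strict") {
    out[ok] <- (rowSums(q < moderate) == 3L) |
      (pmin(q[, 1L], q[, 2L], q[, 3L]) < strong)
  } else {
    out[ok] <- rowSums(q < moderate) >= 2L
  }
  out
}

#' Call biomarkers from a comparison table
#'
#' Applies the consensus rule to each evaluable (gene, drug) comparison of
#' one measure and aggregates passing drugs per gene.
#'
#' @param comparisons Comparison `data.frame` from [screen_panel_genes()]
#'   (or [compare_groups()] rows); must share one measure. Driver-set rows
#'   (`target == "DRIVER_SET"`) are excluded from per-gene calling.
#' @param rule A [screening_rule()].
#' @param adjust `"none"` (default, the raw-threshold consensus design) or
#'   `"BH"`: Benjamini-Hochberg-adjust each test's p-values across the
#'   evaluable comparisons before applying the rule. The adjusted variant
#'   is a deviation from the consensus design, provided for users who want
#'   false-discovery-rate control.
#' @return `data.frame` of calls with columns `gene`, `measure`,
#'   `n_affected_drugs`, `category` (`"1"`, `"2"`, `"3+"`), and
#'   `affected_drugs` (comma-separated); one row per called gene, empty when
#'   nothing passes.
#' @export
call_biomarkers <- function(comparisons, rule = screening_rule("strict"),
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(unique(comparisons$measure)) <= 1L)
  comp <- comparisons[comparisons$target != "DRIVER_SET" &
                        comparisons$evaluable, , drop = FALSE]
  if (adjust == "BH" && nrow(comp) > 0L) {
    comp$p_t <- stats::p.adjust(comp$p_t, "BH")
    comp$p_w <- stats::p.adjust(comp$p_w, "BH")
    comp$p_m <- stats::p.adjust(comp$p_m, "BH")
  }
  empty <- data.frame(gene = character(), measure = character(),
                      n_affected_drugs = integer(), category = character(),
                      affected_drugs = character(), stringsAsFactors = FALSE)
  if (nrow(comp) == 0L) return(empty)
  hit <- passes_rule(comp$p_t, comp$p_w, comp$p_m, rule)
  comp <- comp[hit, , drop = FALSE]
  if (nrow(comp) == 0L) return(empty)
  calls <- lapply(split(comp, comp$target), function(g) {
    drugs <- sort(unique(g$drug))
    data.frame(gene = g$target[1L], measure = g$measure[1L],
               n_affected_drugs = length(drugs),
               category = categorize_by_drug_count(length(drugs)),
               affected_drugs = paste(drugs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize a biomarker call by its affected-drug count
#'
#' @param n_drugs Positive integer count of drugs passing the rule.
#' @return `"1"`, `"2"`, or `"3+"`.
#' @export
categorize_by_drug_count <- function(n_drugs) {
  stopifnot(n_drugs >= 1L)
  ifelse(n_drugs >= 3L, "3+", as.character(n_drugs))
}

#' Evidence tier of a comparison
#'
#' Annotates a comparison by its smallest p-value against the significance
#' ladder: `"strong"` (< 0.01), `"moderate"` (< 0.05), `"weak"` (< 0.1),
#' `"none"` otherwise. The weak tier is annotation only — calling uses the
#' consensus rules.
#'
#' @inheritParams passes_rule
#' @param thresholds The (strong, moderate, weak) ladder.
#' @return Character vector of tiers; `NA` p-values give `"none"`.
#' @export
evidence_tier <- function(p_t, p_w, p_m, thresholds = c(0.01, 0.05, 0.1)) {
  p <- suppressWarnings(pmin(p_t, p_w, p_m, na.rm = TRUE))
  p[!is.finite(p)] <- Inf
  out <- rep("none", length(p))
  out[p < thresholds[3L]] <- "weak"
  out[p < thresholds[2L]] <- "moderate"
  out[p < thresholds[1L]] <- "strong"
  out
}

#' Cross-cancer span of called biomarkers
#'
#' Counts, per gene, the number of distinct panels in which the gene has at
#' least one biomarker call (under any measure).
#'
#' @param calls_by_panel Named list, one calls `data.frame` (from
#'   [call_biomarkers()], possibly row-bound across measures) per panel.
#' @return `data.frame` with columns `gene`, `n_cancers`, sorted by
#'   descending span then alphabetically.
#' @export
cross_cancer_span <- function(calls_by_panel) {
  pairs <- unique(do.call(rbind, lapply(names(calls_by_panel), function(p) {
    calls <- calls_by_panel[[p]]
    if (is.null(calls) || nrow(calls) == 0L) return(NULL)
    data.frame(gene = unique(calls$gene), panel = p, stringsAsFactors = FALSE)
  })))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(gene = character(), n_cancers = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(pairs$gene)
  out <- data.frame(gene = names(tab), n_cancers = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_cancers, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
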