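# Gene-drug sensitivity maps: each cell is a signed reciprocal of the Welch
# t p-value, positive when the mutation is associated with increased drug
# sensitivity (lower EC50 / higher AUC in the mutated group) and negative
# when associated with resistance. Rows and columns are ordered by
# agglomerative hierarchical clustering.

# Direction convention per measure: which way does "more sensitive" point?
measure_direction <- function(measure, lfc_lower_sensitive = TRUE) {
  switch(measure,
    AUC = "higher_sensitive",
    EC50 = "lower_sensitive",
    IC50 = "lower_sensitive",
    LFC = if (lfc_lower_sensitive) "lower_sensitive" else "higher_sensitive",
    stop("unknown measure: ", measure))
}

#' Signed reciprocal-significance score of a comparison
#'
#' The map cell value for one (gene, drug) comparison: the reciprocal of
#' the Welch t p-value, signed by the direction of the mean shift. For EC50
#' and IC50 (lower = more sensitive) the sign is +1 when the mutated group's
#' mean is lower; for AUC (higher = more sensitive) +1 when it is higher.
#' LFC follows the EC50 convention by default (a stronger kill is a lower
#' fold-change); set `lfc_lower_sensitive = FALSE` to flip it. An exact mean
#' tie scores 0. The p-value is floored at 1e-300 so scores stay finite.
#'
#' @param comp One-row comparison from [compare_groups()] (or a list with
#'   `measure`, `mean_mut`, `mean_unmut`, `p_t`).
#' @param lfc_lower_sensitive Sign convention for LFC (default `TRUE`).
#' @return Scalar score, or `NA` for a not-evaluable comparison.
#' @export
signed_significance <- function(comp, lfc_lower_sensitive = TRUE) {
  p <- comp$p_t
  if (is.null(p) || is.na(p)) return(NA_real_)
  stopifnot(p > 0)
  dir <- measure_direction(comp$measure, lfc_lower_sensitive)
  diff <- comp$mean_mut - comp$mean_unmut
  sgn <- if (diff == 0) 0
         else if (dir == "lower_sensitive") -sign(diff)
         else sign(diff)
  sgn / max(p, 1e-300)
}

#' Build a clustered gene-drug sensitivity map
#'
#' Assembles per-cell scores into a gene x drug matrix and orders rows and
#' columns by agglomerative hierarchical clustering (complete linkage,
#' Euclidean distance). Missing cells are imputed as 0 for clustering only
#' and stay `NA` in the stored matrix. Ties in the dendrogram resolve to
#' input order.
#'
#' @param cells `data.frame` with columns `gene`, `drug`, `score` (one row
#'   per available cell). For an SNV map use [signed_significance()] scores;
#'   for a CNV map use Pearson correlations.
#' @param source `"snv_p"` or `"cnv_r"`, recorded as metadata.
#' @param measure Measure label recorded as metadata.
#' @return Object of class `sensitivity_map`: list with `scores` (matrix,
#'   `NA` for missing cells), `row_order`, `col_order` (label permutations),
#'   `source`, `measure`.
#' @export
build_map <- function(cells, source = c("snv_p", "cnv_r"), measure = NA) {
  source <- match.arg(source)
  stopifnot(all(c("gene", "drug", "score") %in% names(cells)))
  cells <- cells[!is.na(cells$score), , drop = FALSE]
  genes <- unique(cells$gene)
  drugs <- unique(cells$drug)
  if (length(genes) < 2L || length(drugs) < 2L)
    stop("need at least 2 genes and 2 drugs with scores; ",
         "report a flat table instead of a map")
  scores <- matrix(NA_real_, length(genes), length(drugs),
                   dimnames = list(genes, drugs))
  scores[cbind(match(cells$gene, genes), match(cells$drug, drugs))] <-
    cells$score
  filled <- scores
  filled[is.na(filled)] <- 0
  row_order <- cluster_order(filled)
  col_order <- cluster_order(t(filled))
  structure(list(scores = scores, row_order = genes[row_order],
                 col_order = drugs[col_order], source = source,
                 measure = measure),
            class = "sensitivity_map")
}

cluster_order <- function(mat) {
  if (nrow(mat) < 2L) return(seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  hc$order
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> %s (%s): %d genes x %d drugs, %d missing cells\n",
              x$source, x$measure, nrow(x$scores), ncol(x$scores),
              sum(is.na(x$scores))))
  invisible(x)
}

#' Export a sensitivity map
#'
#' Writes the score matrix in clustered order as TSV (missing cells encoded
#' as `NA`, never 0), the orders and metadata as JSON, and optionally a PNG
#' heatmap (via the pheatmap package, with the reciprocal scores clipped at
#' +/- 1000 for color mapping only).
#'
#' @param map A `sensitivity_map`.
#' @param path Output path stem; writes `<path>.tsv`, `<path>.json`, and
#'   optionally `<path>.png`.
#' @param image Also render a PNG heatmap (default `FALSE`).
#' @return Invisible character vector of the files written.
#' @export
export_map <- function(map, path, image = FALSE) {
  ordered <- map$scores[map$row_order, map$col_order, drop = FALSE]
  tsv <- paste0(path, ".tsv")
  df <- data.frame(gene = rownames(ordered), as.data.frame(ordered),
                   check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  js <- paste0(path, ".json")
  jsonlite::write_json(list(source = map$source, measure = map$measure,
                            row_order = map$row_order,
                            col_order = map$col_order,
                            n_missing = sum(is.na(map$scores))),
                       js, auto_unbox = TRUE, pretty = TRUE)
  files <- c(tsv, js)
  if (image) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
      stop("the pheatmap package is required for image export")
    png_file <- paste0(path, ".png")
    clipped <- pmin(pmax(ordered, -1000), 1000)
    clipped[is.na(clipped)] <- 0
    grDevices::png(png_file, width = 900, height = 700)
    pheatmap::pheatmap(clipped, cluster_rows = FALSE, cluster_cols = FALSE)
    grDevices::dev.off()
    files <- c(files, png_file)
  }
  invisible(files)
}

#' Read back an exported map matrix
#'
#' @param path The TSV written by [export_map()].
#' @return Numeric matrix with gene rownames and drug colnames.
#' @export
read_map_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Map cells from a comparison table
#'
#' Convenience: converts a comparison table (from [screen_panel_genes()])
#' into the `(gene, drug, score)` cells [build_map()] expects, using
#' [signed_significance()] per row and excluding driver-set rows.
#'
#' @param comparisons Comparison `data.frame` sharing one measure.
#' @param lfc_lower_sensitive Sign convention for LFC.
#' @return `data.frame` with `gene`, `drug`, `score`.
#' @export
comparison_map_cells <- function(comparisons, lfc_lower_sensitive = TRUE) {
  comp <- comparisons[comparisons$target != "DRIVER_SET", , drop = FALSE]
  score <- vapply(seq_len(nrow(comp)), function(i)
    signed_significance(comp[i, ], lfc_lower_sensitive), numeric(1))
  data.frame(gene = comp$target, drug = comp$drug, score = score,
             stringsAsFactors = FALSE)
}
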