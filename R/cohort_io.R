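#' @keywords internal
"_PACKAGE"

# Accepted drug-response measure labels, shared by all readers and screens.
MEASURE_LEVELS <- c("AUC", "EC50", "LFC", "IC50")

#' Accepted drug-response measures
#'
#' Returns the measure labels the pipeline understands: `AUC` (area under the
#' dose-response curve, higher = more sensitive), `EC50`/`IC50` (half-maximal
#' concentrations, lower = more sensitive), and `LFC` (log2 fold-change in
#' viability at a fixed dose).
#'
#' @return Character vector of measure labels.
#' @export
response_measures <- function() MEASURE_LEVELS

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_comma <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_comma && n_tab > 0L) "\t" else ","
}

#' Strip DepMap-style gene headers
#'
#' DepMap matrix exports label gene columns as `"SYMBOL (entrez-id)"`.
#' This strips the parenthetical id, leaving the bare symbol. Stripping an
#' already-plain symbol is a no-op, so the operation is idempotent.
#'
#' @param x Character vector of column headers.
#' @return Character vector of gene symbols.
#' @export
strip_depmap_header <- function(x) {
  sub("\\s*\\([^)]*\\)\\s*$", "", trimws(x))
}

depmap_headers <- function(x) {
  all(grepl("\\([^)]*\\)\\s*$", trimws(x)))
}

read_sample_gene_table <- function(path, dialect) {
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a sample-id column plus gene columns: ", path)
  samples <- as.character(df[[1L]])
  genes <- colnames(df)[-1L]
  if (identical(dialect, "auto")) {
    dialect <- if (depmap_headers(genes)) "depmap-header" else "plain"
  }
  if (identical(dialect, "depmap-header")) genes <- strip_depmap_header(genes)
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(genes))
    stop("duplicate gene symbols after header stripping: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  dimnames(mat) <- list(samples, genes)
  mat
}

#' Read a binary sample-by-gene SNV matrix
#'
#' Reads a CSV/TSV file whose first column holds sample (cell line)
#' identifiers and whose remaining columns are genes, with cell values in
#' `{0, 1}` (1 = the gene carries at least one SNV in that sample). The
#' delimiter is sniffed between comma and tab.
#'
#' @param path Path to the matrix file.
#' @param dialect `"plain"` for bare gene symbols, `"depmap-header"` for
#'   DepMap `"SYMBOL (entrez-id)"` headers, or `"auto"` (default) which picks
#'   `"depmap-header"` only when every gene header carries a parenthetical id.
#' @return A numeric 0/1 matrix with sample-id rownames and gene-symbol
#'   colnames, of class `mutation_matrix`.
#' @export
read_mutation_matrix <- function(path, dialect = c("auto", "plain", "depmap-header")) {
  dialect <- match.arg(dialect)
  mat <- read_sample_gene_table(path, dialect)
  as_mutation_matrix(mat)
}

#' Validate or coerce a mutation matrix
#'
#' @param mat Numeric matrix, rows = samples, columns = genes, values in {0,1}.
#' @return The matrix with class `mutation_matrix`.
#' @export
as_mutation_matrix <- function(mat) {
  stopifnot(is.matrix(mat))
  ok <- is.finite(mat) & (mat == 0 | mat == 1)
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-binary SNV call %s at sample '%s', gene '%s'",
      format(mat[bad[1L, 1L], bad[1L, 2L]]),
      rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  structure(mat, class = c("mutation_matrix", class(mat)))
}

#' Read a sample-by-gene relative copy-number matrix
#'
#' Values are nonnegative relative copy numbers with copy-neutral samples
#' near 1; amplified genes exceed 1. Same file layout and dialect handling as
#' [read_mutation_matrix()].
#'
#' @inheritParams read_mutation_matrix
#' @return A numeric matrix of class `copynumber_matrix`.
#' @export
read_copynumber_matrix <- function(path, dialect = c("auto", "plain", "depmap-header")) {
  dialect <- match.arg(dialect)
  mat <- read_sample_gene_table(path, dialect)
  as_copynumber_matrix(mat)
}

#' @rdname read_copynumber_matrix
#' @param mat Numeric matrix of nonnegative finite copy numbers.
#' @export
as_copynumber_matrix <- function(mat) {
  stopifnot(is.matrix(mat))
  if (any(!is.finite(mat)))
    stop("copy-number matrix contains non-finite values")
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative copy number at sample '%s', gene '%s'",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  structure(mat, class = c("copynumber_matrix", class(mat)))
}

#' Read a long-format drug-response table
#'
#' Expects columns `sample`, `drug`, `measure`, `value` (case-insensitive
#' header). Rows with missing values are dropped and counted in the load
#' report attached as attribute `"load_report"`.
#'
#' @param path Path to the CSV/TSV file.
#' @return A `data.frame` with columns `sample`, `drug`, `measure`, `value`
#'   and attribute `load_report` (a list with `n_read` and `drop_count`).
#' @export
read_response_table <- function(path) {
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  names(df) <- tolower(names(df))
  need <- c("sample", "drug", "measure", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("response table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, need]
  n_read <- nrow(df)
  df$value <- suppressWarnings(as.numeric(df$value))
  keep <- !is.na(df$value)
  drop_count <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  as_response_table(df, load_report = list(n_read = n_read, drop_count = drop_count))
}

#' @rdname read_response_table
#' @param df Data frame with columns `sample`, `drug`, `measure`, `value`.
#' @param load_report Optional list recorded as the `load_report` attribute.
#' @export
as_response_table <- function(df, load_report = NULL) {
  stopifnot(all(c("sample", "drug", "measure", "value") %in% names(df)))
  df$sample <- as.character(df$sample)
  df$drug <- as.character(df$drug)
  df$measure <- as.character(df$measure)
  df$value <- as.numeric(df$value)
  unknown <- setdiff(unique(df$measure), MEASURE_LEVELS)
  if (length(unknown) > 0L)
    stop("unknown measure label(s) ", paste(unknown, collapse = ", "),
         "; accepted measures are {", paste(MEASURE_LEVELS, collapse = ", "), "}")
  key <- paste(df$sample, df$drug, df$measure, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (sample, drug, measure) record: (%s, %s, %s)",
                 dup$sample, dup$drug, dup$measure))
  }
  nonneg <- df$measure %in% c("AUC", "EC50")
  if (any(nonneg & df$value < 0)) {
    bad <- df[nonneg & df$value < 0, ][1L, ]
    stop(sprintf("negative %s value (%g) for sample '%s', drug '%s'",
                 bad$measure, bad$value, bad$sample, bad$drug))
  }
  rownames(df) <- NULL
  if (!is.null(load_report)) attr(df, "load_report") <- load_report
  class(df) <- c("response_table", "data.frame")
  df
}

#' Write a sample-by-gene matrix or response table
#'
#' Round-trip companions of the readers: `write_sample_gene_matrix()` writes a
#' matrix with a leading `sample` column; `write_response_table()` writes the
#' long-format table. Both emit the delimiter implied by the file extension
#' (`.tsv` = tab, otherwise comma).
#'
#' @param mat Matrix with sample rownames and gene colnames.
#' @param path Output path.
#' @export
write_sample_gene_matrix <- function(mat, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_gene_matrix
#' @param resp A response table (see [read_response_table()]).
#' @export
write_response_table <- function(resp, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(resp), path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a cancer panel
#'
#' A panel names one cancer's drugs, its putative driver genes (e.g. the
#' Cancer Gene Census set for that cancer), and the response measures to
#' analyze.
#'
#' @param cancer_code Short cancer label (e.g. `"BRCA"`, `"SKCM"`).
#' @param drugs Character vector of drug names (non-empty, unique).
#' @param driver_genes Character vector of gene symbols (non-empty, unique;
#'   upper-cased on construction).
#' @param measures Subset of [response_measures()].
#' @return A list of class `cancer_panel`.
#' @export
cancer_panel <- function(cancer_code, drugs, driver_genes,
                         measures = c("AUC", "EC50")) {
  drugs <- as.character(drugs)
  driver_genes <- toupper(as.character(driver_genes))
  if (length(drugs) == 0L) stop("panel '", cancer_code, "' has no drugs")
  if (length(driver_genes) == 0L)
    stop("panel '", cancer_code, "' has no driver genes")
  if (anyDuplicated(drugs)) stop("duplicate drugs in panel '", cancer_code, "'")
  if (anyDuplicated(driver_genes))
    stop("duplicate driver genes in panel '", cancer_code, "'")
  bad <- setdiff(measures, MEASURE_LEVELS)
  if (length(bad) > 0L)
    stop("unknown measure(s) ", paste(bad, collapse = ", "),
         " in panel '", cancer_code, "'")
  structure(list(cancer_code = as.character(cancer_code), drugs = drugs,
                 driver_genes = driver_genes, measures = measures),
            class = "cancer_panel")
}

#' Load a panel configuration file
#'
#' The configuration is YAML with one entry per cancer:
#' ```yaml
#' SKCM:
#'   drugs: [dabrafenib, vemurafenib, ...]
#'   driver_genes: [BRAF, NRAS, ...]
#'   measures: [AUC, EC50, LFC]
#' ```
#'
#' @param path Path to the YAML file.
#' @return Named list of [cancer_panel()] objects in file order.
#' @export
load_panel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0L) stop("empty panel configuration: ", path)
  panels <- lapply(names(cfg), function(code) {
    entry <- cfg[[code]]
    cancer_panel(code, drugs = entry$drugs, driver_genes = entry$driver_genes,
                 measures = if (is.null(entry$measures)) c("AUC", "EC50")
                            else entry$measures)
  })
  names(panels) <- names(cfg)
  panels
}

#' @export
print.cancer_panel <- function(x, ...) {
  cat(sprintf("<cancer_panel> %s: %d drugs, %d driver genes, measures {%s}\n",
              x$cancer_code, length(x$drugs), length(x$driver_genes),
              paste(x$measures, collapse = ", ")))
  invisible(x)
}

# Join helper: samples present in every supplied id set; drops are counted.
joint_samples <- function(..., warn = TRUE) {
  sets <- list(...)
  common <- Reduce(intersect, sets)
  n_drop <- length(unique(unlist(sets))) - length(common)
  if (warn && n_drop > 0L)
    message(n_drop, " sample(s) absent from at least one input were dropped")
  common
}
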