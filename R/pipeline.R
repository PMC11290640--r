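# End-to-end panel runs: transform selection -> driver-set comparison ->
# per-gene comparisons -> consensus calls -> sensitivity map, per
# (panel, measure), plus the CNV analogue. Everything is deterministic given
# the inputs; file output is optional.

#' Run the SNV screen for one or more panels
#'
#' For every panel and every measure the panel declares: fit the transform
#' on the panel's pooled measure values, compare the driver-set partition
#' per drug, compare every driver gene per drug, apply the strict and
#' relaxed consensus rules, categorize calls by drug count, and (when at
#' least 2 genes and 2 drugs have scores) build the signed-significance map.
#'
#' @param mutations A `mutation_matrix` (or path to one).
#' @param responses A `response_table` (or path).
#' @param panels A single [cancer_panel()] or (named) list of panels.
#' @param transform_values Apply the measure transform before testing
#'   (default `TRUE`); `FALSE` runs every comparison on the raw scale.
#' @param min_group Minimum per-group size for evaluability.
#' @param out_dir Optional directory; when given, comparison tables, calls,
#'   maps and a JSON run report are written there.
#' @return Named list (one entry per panel) of class `run_report` objects:
#'   each holds, per measure, the `transform_spec`, driver-set comparisons,
#'   the gene comparison table, `strict_calls`, `relaxed_calls`, and `map`;
#'   plus `span`, the cross-cancer span table over all panels.
#' @export
run_snv_screen <- function(mutations, responses, panels,
                           transform_values = TRUE, min_group = 2L,
                           out_dir = NULL) {
  if (is.character(mutations)) mutations <- read_mutation_matrix(mutations)
  if (is.character(responses)) responses <- read_response_table(responses)
  panels <- as_panel_list(panels)
  common <- intersect(rownames(mutations), unique(responses$sample))
  if (length(common) == 0L)
    stop("no overlapping samples between the mutation matrix and the response table")
  reports <- list()
  for (panel in panels) {
    per_measure <- list()
    for (measure in panel$measures) {
      pool <- responses$value[responses$measure == measure &
                                responses$drug %in% panel$drugs &
                                responses$sample %in% common]
      if (length(pool) < 20L) next
      tr <- if (transform_values) select_and_apply_transform(measure, pool)$spec
            else identity_transform_spec(measure)
      part <- partition_by_driver_set(mutations, panel$driver_genes)
      set_rows <- do.call(rbind, lapply(panel$drugs, function(d)
        compare_groups(responses, part, d, measure, tr,
                       target = "DRIVER_SET", min_group = min_group)))
      gene_rows <- screen_panel_genes(mutations, responses, panel, measure,
                                      tr, min_group = min_group)
      gene_rows$evidence <- evidence_tier(gene_rows$p_t, gene_rows$p_w,
                                          gene_rows$p_m)
      strict <- call_biomarkers(gene_rows, screening_rule("strict"))
      relaxed <- call_biomarkers(gene_rows, screening_rule("relaxed"))
      cells <- comparison_map_cells(gene_rows)
      map <- tryCatch(build_map(cells, "snv_p", measure),
                      error = function(e) NULL)
      per_measure[[measure]] <- list(
        transform = tr, driver_set = set_rows, comparisons = gene_rows,
        strict_calls = strict, relaxed_calls = relaxed, map = map,
        n_not_evaluable = sum(!gene_rows$evaluable),
        n_evaluated = sum(gene_rows$evaluable))
    }
    reports[[panel$cancer_code]] <- structure(
      list(panel = panel, measures = per_measure,
           n_samples_joined = length(common)),
      class = "run_report")
  }
  span_input <- lapply(reports, function(r)
    do.call(rbind, lapply(r$measures, function(m) m$strict_calls)))
  attr(reports, "span") <- cross_cancer_span(span_input)
  if (!is.null(out_dir)) write_snv_outputs(reports, out_dir)
  reports
}

#' Run the CNV screen for one or more panels
#'
#' Per (panel, measure): max-driver-CNV group assignment and per-drug group
#' summaries, continuous per-gene CNV associations, and a Pearson-r map.
#'
#' @inheritParams run_snv_screen
#' @param copynumber A `copynumber_matrix` (or path).
#' @param bin_mode Binning mode for group assignment, see [bin_cnv()].
#' @return Named list of per-panel reports with `groups`, per-measure
#'   `group_summaries`, `associations`, and `map`.
#' @export
run_cnv_screen <- function(copynumber, responses, panels,
                           transform_values = TRUE,
                           bin_mode = c("nearest", "ceiling"),
                           out_dir = NULL) {
  bin_mode <- match.arg(bin_mode)
  if (is.character(copynumber)) copynumber <- read_copynumber_matrix(copynumber)
  if (is.character(responses)) responses <- read_response_table(responses)
  panels <- as_panel_list(panels)
  common <- intersect(rownames(copynumber), unique(responses$sample))
  if (length(common) == 0L)
    stop("no overlapping samples between the copy-number matrix and the response table")
  reports <- list()
  for (panel in panels) {
    groups <- max_driver_cnv_groups(copynumber, panel$driver_genes, bin_mode)
    per_measure <- list()
    for (measure in panel$measures) {
      pool <- responses$value[responses$measure == measure &
                                responses$drug %in% panel$drugs &
                                responses$sample %in% common]
      if (length(pool) < 20L) next
      tr <- if (transform_values) select_and_apply_transform(measure, pool)$spec
            else identity_transform_spec(measure)
      summaries <- lapply(stats::setNames(panel$drugs, panel$drugs),
                          function(d)
        cnv_group_response_summary(groups, responses, d, measure, tr))
      assoc <- screen_panel_cnv(copynumber, responses, panel, measure, tr)
      cells <- data.frame(gene = assoc$gene, drug = assoc$drug,
                          score = assoc$p_cor, stringsAsFactors = FALSE)
      map <- tryCatch(build_map(cells, "cnv_r", measure),
                      error = function(e) NULL)
      per_measure[[measure]] <- list(transform = tr,
                                     group_summaries = summaries,
                                     associations = assoc, map = map)
    }
    reports[[panel$cancer_code]] <- structure(
      list(panel = panel, groups = groups, measures = per_measure,
           n_samples_joined = length(common)),
      class = "run_report")
  }
  if (!is.null(out_dir)) write_cnv_outputs(reports, out_dir)
  reports
}

as_panel_list <- function(panels) {
  if (inherits(panels, "cancer_panel")) panels <- list(panels)
  stopifnot(all(vapply(panels, inherits, logical(1), "cancer_panel")))
  panels
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> panel %s, %d joined samples, measures: %s\n",
              x$panel$cancer_code, x$n_samples_joined,
              paste(names(x$measures), collapse = ", ")))
  invisible(x)
}

write_snv_outputs <- function(reports, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- character()
  for (code in names(reports)) {
    r <- reports[[code]]
    for (measure in names(r$measures)) {
      m <- r$measures[[measure]]
      stem <- file.path(out_dir, paste0(code, "_", measure))
      comp_file <- paste0(stem, "_comparisons.tsv")
      utils::write.table(m$comparisons, comp_file, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      calls_file <- paste0(stem, "_calls.json")
      jsonlite::write_json(
        list(transform = unclass(m$transform),
             strict = m$strict_calls, relaxed = m$relaxed_calls,
             n_evaluated = m$n_evaluated,
             n_not_evaluable = m$n_not_evaluable),
        calls_file, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
      manifest <- c(manifest, comp_file, calls_file)
      if (!is.null(m$map))
        manifest <- c(manifest, export_map(m$map, paste0(stem, "_map")))
    }
  }
  span <- attr(reports, "span")
  if (!is.null(span) && nrow(span) > 0L) {
    span_file <- file.path(out_dir, "cross_cancer_span.tsv")
    utils::write.table(span, span_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, span_file)
  }
  invisible(manifest)
}

write_cnv_outputs <- function(reports, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- character()
  for (code in names(reports)) {
    r <- reports[[code]]
    for (measure in names(r$measures)) {
      m <- r$measures[[measure]]
      stem <- file.path(out_dir, paste0(code, "_", measure))
      assoc_file <- paste0(stem, "_cnv_associations.tsv")
      utils::write.table(m$associations, assoc_file, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest <- c(manifest, assoc_file)
      if (!is.null(m$map))
        manifest <- c(manifest, export_map(m$map, paste0(stem, "_cnv_map")))
    }
  }
  invisible(manifest)
}
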