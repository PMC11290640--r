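# Bundled example data.

#' Bundled cancer panel configuration
#'
#' Path to (or parsed content of) the bundled panel configuration covering
#' seven cancers (BRCA, NSCLC, CRC, PRAD, SKCM, CML, GB) with their screened
#' drugs, CGC driver gene sets, and response measures.
#'
#' @param parse Return parsed panels (default) instead of the file path.
#' @return A named list of [cancer_panel()]s, or the file path.
#' @export
ccle_panel_config <- function(parse = TRUE) {
  path <- system.file("extdata", "ccle_panels.yaml", package = "driverscreen")
  if (parse) load_panel_config(path) else path
}

#' Worked example: GDSC2 breast-cancer IC50 SNV comparisons
#'
#' A published summary of six gene-drug comparisons from an SNV screen of
#' breast-cancer drugs against GDSC2 IC50 values: per comparison, the Welch
#' t (`p_t`), Mann-Whitney (`p_w`) and median-test (`p_m`) p-values and the
#' mutated/unmutated group sizes. Under the strict consensus rule exactly
#' two of the six genes are called (ERBB2, PIK3CA); under the relaxed rule
#' all six are.
#'
#' @return `data.frame` with columns `gene`, `drug`, `p_t`, `p_w`, `p_m`,
#'   `n_mut`, `n_unmut`.
#' @export
gdsc2_brca_ic50_example <- function() {
  path <- system.file("extdata", "gdsc2_brca_ic50_comparisons.tsv",
                      package = "driverscreen")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
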