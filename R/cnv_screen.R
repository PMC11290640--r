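# Copy-number screening: integer binning of relative copy numbers, grouping
# by the maximum driver-gene CNV, and per-gene association of continuous CNV
# with transformed drug response via three correlations and two fits.

#' Bin a relative copy number to an integer
#'
#' Two binning modes: `"nearest"` rounds half away from zero (1.4 -> 1,
#' 3.5 -> 4) and is the default for the max-driver-CNV grouping; `"ceiling"`
#' rounds up (1.2 -> 2), which dichotomizes a copy-neutral cohort around 1
#' into two groups and suits small cancer-specific sample sets. The modes
#' agree on exact integers.
#'
#' @param value Nonnegative numeric vector.
#' @param mode `"nearest"` or `"ceiling"`.
#' @return Integer vector.
#' @export
bin_cnv <- function(value, mode = c("nearest", "ceiling")) {
  mode <- match.arg(mode)
  if (any(value < 0)) stop("copy numbers must be nonnegative")
  if (mode == "nearest") as.integer(floor(value + 0.5))
  else as.integer(ceiling(value))
}

#' Group samples by their maximum driver-gene copy number
#'
#' For each sample, takes the maximum copy number over the panel's driver
#' genes, bins it, and collapses bins of 4 or more into `"4+"`. Bin 0
#' (homozygous-deletion territory) is kept as its own label; trend summaries
#' use only bins 1 to 4+.
#'
#' @param cn A copy-number matrix (samples x genes).
#' @param drivers Character vector of driver gene symbols.
#' @param mode Binning mode, see [bin_cnv()].
#' @return `data.frame` with columns `sample` and `bin` (factor with levels
#'   `0, 1, 2, 3, 4+`); every sample appears exactly once.
#' @export
max_driver_cnv_groups <- function(cn, drivers, mode = c("nearest", "ceiling")) {
  mode <- match.arg(mode)
  present <- intersect(drivers, colnames(cn))
  if (length(present) == 0L)
    stop("none of the driver genes are present in the copy-number matrix")
  mx <- apply(cn[, present, drop = FALSE], 1L, max)
  b <- bin_cnv(mx, mode)
  lab <- ifelse(b >= 4L, "4+", as.character(b))
  data.frame(sample = rownames(cn),
             bin = factor(lab, levels = c("0", "1", "2", "3", "4+")),
             stringsAsFactors = FALSE)
}

#' Per-bin response summaries for the max-driver-CNV grouping
#'
#' Joins the group assignment with one (drug, measure) and reports per-bin
#' counts, means, and quartiles, plus a monotone-trend index: the Kendall
#' tau between the numeric bin (1..4, over bins 1 to 4+ only) and the
#' response value.
#'
#' @param groups Assignment from [max_driver_cnv_groups()].
#' @param resp Response table.
#' @param drug,measure The response slice to summarize.
#' @param transform Optional `transform_spec` applied to the values.
#' @return List with `summary` (`data.frame`: `bin`, `n`, `mean`, `q25`,
#'   `median`, `q75`; quartiles `NA` when `n < 2`) and `trend_tau`.
#' @export
cnv_group_response_summary <- function(groups, resp, drug, measure,
                                       transform = identity_transform_spec(measure)) {
  sub <- resp[resp$drug == drug & resp$measure == measure, ]
  merged <- merge(groups, sub, by = "sample")
  merged$value <- apply_transform(transform, merged$value)
  stats_by_bin <- lapply(levels(groups$bin), function(lv) {
    v <- merged$value[merged$bin == lv]
    if (length(v) == 0L) return(NULL)
    q <- if (length(v) >= 2L) stats::quantile(v, c(0.25, 0.5, 0.75),
                                              names = FALSE)
         else rep(NA_real_, 3L)
    data.frame(bin = lv, n = length(v), mean = mean(v),
               q25 = q[1L], median = q[2L], q75 = q[3L],
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, stats_by_bin)
  trend <- merged[merged$bin != "0", , drop = FALSE]
  trend_tau <- NA_real_
  bin_num <- match(as.character(trend$bin), c("1", "2", "3", "4+"))
  if (nrow(trend) >= 3L && length(unique(bin_num)) > 1L &&
      stats::var(trend$value) > 0)
    trend_tau <- stats::cor(bin_num, trend$value, method = "kendall")
  list(summary = summary, trend_tau = trend_tau)
}

#' Associate one gene's continuous copy number with drug response
#'
#' Uses the unbinned copy number against the (optionally transformed)
#' response: Pearson, Spearman, and Kendall tau-b coefficients plus ordinary
#' and Huber-robust linear fits. Samples lacking either value are dropped;
#' the record is marked not-evaluable when fewer than 3 pairs remain or the
#' copy number is constant.
#'
#' @param cn Copy-number matrix.
#' @param resp Response table.
#' @param gene Gene symbol (column of `cn`).
#' @param drug,measure The response slice.
#' @param transform Optional `transform_spec`.
#' @return One-row `data.frame`: `gene`, `drug`, `measure`, `n`, `p_cor`,
#'   `s_rho`, `k_tau`, `lm_slope`, `lm_intercept`, `rlm_slope`,
#'   `rlm_intercept`, `evaluable`.
#' @export
cnv_gene_association <- function(cn, resp, gene, drug, measure,
                                 transform = identity_transform_spec(measure)) {
  if (!gene %in% colnames(cn))
    stop("gene '", gene, "' not in copy-number matrix")
  sub <- resp[resp$drug == drug & resp$measure == measure, ]
  common <- intersect(sub$sample, rownames(cn))
  x <- cn[common, gene]
  y <- apply_transform(transform,
                       stats::setNames(sub$value, sub$sample)[common])
  row <- data.frame(gene = gene, drug = drug, measure = measure,
                    n = length(common), p_cor = NA_real_, s_rho = NA_real_,
                    k_tau = NA_real_, lm_slope = NA_real_,
                    lm_intercept = NA_real_, rlm_slope = NA_real_,
                    rlm_intercept = NA_real_, evaluable = FALSE,
                    stringsAsFactors = FALSE)
  if (length(common) < 3L || stats::var(x) == 0 || stats::var(y) == 0)
    return(row)
  row$p_cor <- correlation(x, y, "pearson")
  row$s_rho <- correlation(x, y, "spearman")
  row$k_tau <- correlation(x, y, "kendall")
  lmf <- linear_fit(x, y)
  row$lm_slope <- lmf$slope; row$lm_intercept <- lmf$intercept
  rlmf <- tryCatch(huber_fit(x, y), error = function(e) NULL)
  if (!is.null(rlmf)) {
    row$rlm_slope <- rlmf$slope; row$rlm_intercept <- rlmf$intercept
  }
  row$evaluable <- TRUE
  row
}

#' Screen every driver gene's CNV against every drug of a panel
#'
#' @param cn Copy-number matrix.
#' @param resp Response table.
#' @param panel A [cancer_panel()].
#' @param measure Measure label.
#' @param transform Optional `transform_spec`.
#' @return `data.frame` of [cnv_gene_association()] rows.
#' @export
screen_panel_cnv <- function(cn, resp, panel, measure,
                             transform = identity_transform_spec(measure)) {
  genes <- intersect(panel$driver_genes, colnames(cn))
  rows <- list()
  for (gene in genes) {
    for (drug in panel$drugs) {
      rows[[length(rows) + 1L]] <-
        cnv_gene_association(cn, resp, gene, drug, measure, transform)
    }
  }
  do.call(rbind, rows)
}
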