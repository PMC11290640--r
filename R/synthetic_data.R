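# Synthetic cohorts with the statistical structure the screens assume:
# near-normal AUC (mean 1), lognormal EC50, signed near-normal LFC, relative
# copy numbers ~ Normal(1, 0.15) truncated at 0 with rare uniform
# amplifications, and independent Bernoulli driver SNVs at gene-specific
# frequencies. Planted gene-drug effects are additive on the transformed
# analysis scale (for EC50, on the log scale), so an effect of size delta
# shifts the mutated group by delta pooled standard deviations and power is
# analytically checkable against the t-test power function.

#' Specify a synthetic cohort
#'
#' @param n_samples Number of cell lines.
#' @param gene_freqs Named numeric vector: per-gene SNV frequency in (0, 1).
#' @param drugs Character vector of drug names.
#' @param measures Subset of [response_measures()].
#' @param auc_mean,auc_sd AUC base model: Normal truncated at 0
#'   (defaults 1.0, 0.15).
#' @param ec50_meanlog,ec50_sdlog EC50 base model: lognormal (defaults 0.5,
#'   1.0, i.e. a median near 1.6 concentration units spread over roughly two
#'   orders of magnitude, as in a multi-step dilution screen).
#' @param lfc_mean,lfc_sd LFC base model: Normal (defaults 0, 1).
#' @param cnv_mean,cnv_sd Copy-number base model: Normal truncated at 0
#'   (defaults 1.0, 0.15).
#' @param p_amp Per-(sample, gene) amplification probability; amplified
#'   copy numbers are drawn Uniform(2, 6) (default 0.01).
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, gene_freqs, drugs,
                        measures = c("AUC", "EC50", "LFC"),
                        auc_mean = 1.0, auc_sd = 0.15,
                        ec50_meanlog = 0.5, ec50_sdlog = 1.0,
                        lfc_mean = 0, lfc_sd = 1,
                        cnv_mean = 1.0, cnv_sd = 0.15,
                        p_amp = 0.01, seed = 1L) {
  stopifnot(n_samples >= 1L, length(gene_freqs) >= 1L, length(drugs) >= 1L)
  if (is.null(names(gene_freqs)) || any(names(gene_freqs) == ""))
    stop("gene_freqs must be a named vector of per-gene frequencies")
  if (any(gene_freqs <= 0 | gene_freqs >= 1))
    stop("mutation frequencies must lie strictly in (0, 1)")
  if (auc_sd <= 0 || ec50_sdlog <= 0 || lfc_sd <= 0 || cnv_sd <= 0)
    stop("scale parameters must be positive")
  if (p_amp < 0 || p_amp >= 1) stop("p_amp must lie in [0, 1)")
  bad <- setdiff(measures, MEASURE_LEVELS)
  if (length(bad) > 0L) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  structure(list(n_samples = as.integer(n_samples), gene_freqs = gene_freqs,
                 drugs = as.character(drugs), measures = measures,
                 auc_mean = auc_mean, auc_sd = auc_sd,
                 ec50_meanlog = ec50_meanlog, ec50_sdlog = ec50_sdlog,
                 lfc_mean = lfc_mean, lfc_sd = lfc_sd,
                 cnv_mean = cnv_mean, cnv_sd = cnv_sd,
                 p_amp = p_amp, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Null cohort spec with driver-like mutation frequencies
#'
#' Convenience constructor: genes `G1..Gk`, drugs `D1..Dm`, per-gene SNV
#' frequencies drawn log-uniformly in \[0.05, 0.3\] (driver genes mutate far
#' more often than passengers), default response models, and an empty truth.
#'
#' @param n_samples,n_genes,n_drugs Positive sizes.
#' @param seed Integer seed (controls both the frequency draw and, later,
#'   cohort generation).
#' @return List with `spec` (a [cohort_spec()]) and `truth` (an empty
#'   [synthetic_truth()]).
#' @export
make_null_spec <- function(n_samples, n_genes, n_drugs, seed = 1L) {
  stopifnot(n_samples >= 1L, n_genes >= 1L, n_drugs >= 1L)
  set.seed(seed)
  freqs <- exp(stats::runif(n_genes, log(0.05), log(0.3)))
  names(freqs) <- paste0("G", seq_len(n_genes))
  spec <- cohort_spec(n_samples, freqs, paste0("D", seq_len(n_drugs)),
                      seed = seed)
  list(spec = spec, truth = synthetic_truth())
}

#' Ground-truth planted effects
#'
#' @param snv_effects `data.frame` with columns `gene`, `drug`, `measure`,
#'   `delta` (effect size in pooled-SD units on the transformed scale),
#'   `direction` (`"sensitizing"` or `"resistant"`); may be empty.
#' @param cnv_effects `data.frame` with columns `gene`, `drug`, `measure`,
#'   `beta` (slope per copy on the transformed scale); may be empty.
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(snv_effects = NULL, cnv_effects = NULL) {
  if (is.null(snv_effects))
    snv_effects <- data.frame(gene = character(), drug = character(),
                              measure = character(), delta = numeric(),
                              direction = character(),
                              stringsAsFactors = FALSE)
  if (is.null(cnv_effects))
    cnv_effects <- data.frame(gene = character(), drug = character(),
                              measure = character(), beta = numeric(),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "drug", "measure", "delta", "direction") %in%
                  names(snv_effects)),
            all(c("gene", "drug", "measure", "beta") %in% names(cnv_effects)))
  if (nrow(snv_effects) > 0L &&
      !all(snv_effects$direction %in% c("sensitizing", "resistant")))
    stop("snv_effects$direction must be 'sensitizing' or 'resistant'")
  structure(list(snv_effects = snv_effects, cnv_effects = cnv_effects),
            class = "synthetic_truth")
}

rtruncnorm0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Direction of a sensitizing shift on the analysis scale of each measure:
# sensitizing = higher AUC, lower (log-)EC50, lower LFC.
shift_sign <- function(measure, direction) {
  s <- if (direction == "sensitizing") 1 else -1
  if (measure == "AUC") s else -s
}

base_sd_on_analysis_scale <- function(spec, measure) {
  switch(measure,
    AUC = spec$auc_sd,    # analysis scale = raw (identity transform)
    EC50 = spec$ec50_sdlog,  # analysis scale = log
    IC50 = spec$ec50_sdlog,
    LFC = spec$lfc_sd,
    stop("unknown measure: ", measure))
}

#' Generate a synthetic cohort with planted effects
#'
#' Draws independent Bernoulli SNVs at the spec's per-gene frequencies, a
#' copy-number matrix from the truncated-normal-plus-amplification model,
#' and responses from the per-measure base models. Planted SNV effects add
#' `delta` pooled standard deviations on the analysis scale (raw for AUC and
#' LFC, log for EC50/IC50) to every mutated sample's response; planted CNV
#' effects add `beta * (CNV - 1)`. Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [synthetic_truth()]; defaults to no planted effects.
#' @return List of class `synthetic_cohort` with `mutations`
#'   (`mutation_matrix`), `copynumber` (`copynumber_matrix`), `responses`
#'   (`response_table`), and `truth`.
#' @export
generate_cohort <- function(spec, truth = synthetic_truth()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "synthetic_truth"))
  genes <- names(spec$gene_freqs)
  for (tab in list(truth$snv_effects, truth$cnv_effects)) {
    if (nrow(tab) == 0L) next
    bad_g <- setdiff(tab$gene, genes)
    bad_d <- setdiff(tab$drug, spec$drugs)
    bad_m <- setdiff(tab$measure, spec$measures)
    if (length(c(bad_g, bad_d, bad_m)) > 0L)
      stop("planted effect references unknown gene/drug/measure: ",
           paste(c(bad_g, bad_d, bad_m), collapse = ", "))
  }
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  calls <- vapply(genes, function(g)
    stats::rbinom(n, 1L, spec$gene_freqs[[g]]), numeric(n))
  calls <- matrix(calls, nrow = n, dimnames = list(samples, genes))
  mut <- as_mutation_matrix(calls)

  cnv <- matrix(rtruncnorm0(n * length(genes), spec$cnv_mean, spec$cnv_sd),
                nrow = n, dimnames = list(samples, genes))
  amp <- matrix(stats::runif(n * length(genes)) < spec$p_amp, nrow = n)
  cnv[amp] <- stats::runif(sum(amp), 2, 6)
  cnv <- as_copynumber_matrix(cnv)

  records <- list()
  for (measure in spec$measures) {
    for (drug in spec$drugs) {
      base <- switch(measure,
        AUC = rtruncnorm0(n, spec$auc_mean, spec$auc_sd),
        EC50 = stats::rnorm(n, spec$ec50_meanlog, spec$ec50_sdlog),
        IC50 = stats::rnorm(n, spec$ec50_meanlog, spec$ec50_sdlog),
        LFC = stats::rnorm(n, spec$lfc_mean, spec$lfc_sd))
      # EC50/IC50 are built on the log scale and exponentiated at the end
      shift <- numeric(n)
      sd0 <- base_sd_on_analysis_scale(spec, measure)
      eff <- truth$snv_effects
      eff <- eff[eff$drug == drug & eff$measure == measure, , drop = FALSE]
      if (nrow(eff) > 0L) {
        for (i in seq_len(nrow(eff))) {
          carrier <- calls[, eff$gene[i]] == 1
          shift[carrier] <- shift[carrier] +
            shift_sign(measure, eff$direction[i]) * eff$delta[i] * sd0
        }
      }
      ceff <- truth$cnv_effects
      ceff <- ceff[ceff$drug == drug & ceff$measure == measure, , drop = FALSE]
      if (nrow(ceff) > 0L) {
        for (i in seq_len(nrow(ceff))) {
          shift <- shift + ceff$beta[i] * (cnv[, ceff$gene[i]] - 1)
        }
      }
      value <- base + shift
      if (measure %in% c("EC50", "IC50")) value <- exp(value)
      if (measure == "AUC") value <- pmax(value, 0)
      records[[length(records) + 1L]] <-
        data.frame(sample = samples, drug = drug, measure = measure,
                   value = value, stringsAsFactors = FALSE)
    }
  }
  resp <- as_response_table(do.call(rbind, records))
  structure(list(mutations = mut, copynumber = cnv, responses = resp,
                 truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort as the pipeline's standard input files
#'
#' Writes `mutations.csv`, `copynumber.csv`, and `responses.csv` under
#' `dir`, in the formats [read_mutation_matrix()], [read_copynumber_matrix()]
#' and [read_response_table()] accept, so a generated cohort runs through
#' the pipeline with no special-casing.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisible named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mutations = file.path(dir, "mutations.csv"),
             copynumber = file.path(dir, "copynumber.csv"),
             responses = file.path(dir, "responses.csv"))
  write_sample_gene_matrix(cohort$mutations, paths[["mutations"]])
  write_sample_gene_matrix(cohort$copynumber, paths[["copynumber"]])
  write_response_table(cohort$responses, paths[["responses"]])
  invisible(paths)
}
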