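---
title: "Screening driver mutations for drug-response biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening driver mutations for drug-response biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverscreen)
```

## The problem

Cancer cell-line screens measure how hundreds of cell lines respond to
hundreds of compounds, summarized per (cell line, drug) as AUC (area under
the dose-response viability curve; here higher = more sensitive), EC50 or
IC50 (half-maximal concentrations; lower = more sensitive), or LFC (log2
fold-change in viability at a fixed dose). The same cell lines carry
genomic annotations: a binary SNV call per gene, and a relative copy
number per gene centered near 1. Because driver genes (e.g. the Cancer
Gene Census set for a cancer) mutate at much higher rates than passengers,
restricting attention to a cancer's driver set gives mutated groups large
enough for two-sample inference.

`driverscreen` asks, for each (driver gene, drug, measure): does mutation
status shift drug response? It answers with three tests, a consensus rule,
copy-number trend and correlation analyses, and a clustered gene–drug map
of signed significance scores.

## Response normalization

Group location tests — the Welch t-test in particular — behave best on
near-normal data, so each (panel, measure) pool (values pooled across the
panel's drugs) is transformed once and mean-centered:

* **Nonnegative measures (AUC, EC50, IC50).** The Box-Cox
  profile-likelihood \(\hat\lambda\) is estimated over \([-2, 2]\) (0.01
  grid, golden-section refinement — deterministic and reproducible to
  ~1e-6). If \(|\hat\lambda - 1| \le 0.25\) the data are already
  sufficiently normal and the identity is used; if \(|\hat\lambda| \le
  0.25\) a log transform is used; otherwise Box-Cox at \(\hat\lambda\).
  The \(\pm 0.25\) window is a fixed design choice: it cleanly separates
  "close to 1" from "close to 0", the only two regimes screening data
  realistically occupy (AUC pools select identity, EC50/IC50 pools select
  log).
* **Measures with negative values (LFC).** Yeo-Johnson at the MLE
  \(\hat\lambda\), the natural power-transform family on the whole real
  line.

After the transform, the pool mean is subtracted and recorded, so group
means downstream are shifts around 0 and a stored `transform_spec`
replays the identical mapping on new values.

Normality is reported descriptively with a one-sample Kolmogorov-Smirnov
statistic against the moment-fitted normal. Since mean and sd are
estimated from the same data, this KS p-value is anti-conservative (the
Lilliefors effect); it is a reporting index, not a gatekeeper — the
transform choice depends only on \(\hat\lambda\).

Identifiability caveat: \(\lambda\) is well identified only when the pool
has non-trivial relative spread. For a positive near-normal pool with
coefficient of variation 0.15 at \(n = 500\), \(\hat\lambda\) has
standard error around 0.2, so the identity-vs-log decision is reliable at
the pool level (CV \(\gtrsim 0.25\), as in multi-drug pools) rather than
for narrow single-drug slices. This is a property of the Box-Cox
likelihood, not of the estimator; the calibration study in the package's
acceptance checks therefore uses CV 0.3 for the near-normal pool.

## The three tests and the consensus rule

For each (gene, drug, measure), samples split into mutated vs unmutated
groups (for the driver-set analysis: any mutation across the panel's
drivers). Three two-sided tests run on the transformed values:

1. **Welch t** — location shift without equal-variance assumption;
2. **Mann-Whitney-Wilcoxon** — rank-sum; exact by enumeration when both
   groups are under 50 with no ties, otherwise normal approximation with
   tie and continuity corrections;
3. **Brown-Mood median test** — pooled values dichotomized at the common
   median (ties at the median count as "≤ median"; the convention is
   fixed and documented because different implementations disagree), then
   a 2×2 Pearson chi-square on 1 df, no continuity correction by default
   (a Yates flag exists).

A (gene, drug) pair is **called** under the *strict* rule when all three
p-values are < 0.05 or any one is < 0.01, and under the *relaxed* rule
when at least two are < 0.05. Thresholds are strict inequalities. The
0.1 level is an annotation tier ("weak evidence") only — never used for
calling. Neither rule implies the other in general: a triple like
(0.005, 0.2, 0.3) passes strict but not relaxed; for triples with all
p ≥ 0.01 strict does imply relaxed. No multiple-testing correction is
applied by default, matching the raw-threshold ladder this consensus
design expects; the per-comparison strict false-call rate under the null
is about 2–4% (the three tests are strongly correlated), which the
acceptance checks measure directly.

Calls aggregate per gene into drug-count categories {1, 2, 3+}, and
genes are ranked across panels by their cross-cancer span (number of
panels with at least one call). Comparisons where either group has fewer
than 2 response values are reported as not-evaluable rather than
silently dropped; 2 is deliberately permissive (screens of rare drivers
legitimately compare n = 2 against hundreds), and the group sizes are
always reported alongside the p-values so readers can weigh them.

A known numerical caveat, measured rather than hidden: the uncorrected
asymptotic median test is slightly liberal at moderate sizes — at
n = 50/50 its exact size at nominal 0.05 is 0.071 (the above-median
count is Hypergeometric(50, 50, 50) and rejection is |a − 25| ≥ 5).
The Yates-corrected variant has size 0.027. The default stays
uncorrected because the closed-form chi-square is the documented
operation contract; users wanting a conservative median test can pass
`yates = TRUE`.

## Copy-number analyses

Relative copy numbers (neutral ≈ 1) are used two ways:

* **Grouped:** each sample's maximum copy number over the panel's driver
  genes is binned to an integer; bins ≥ 4 collapse into "4+". The default
  binning is nearest-integer (half away from zero); a ceiling mode is
  provided for small cancer-specific cohorts, where rounding up splits a
  copy-neutral cohort around 1 into two usable groups. Bin 0 — the
  homozygous-deletion regime — is reported separately and excluded from
  the {1, 2, 3, 4+} trend, which is defined for amplification. Per-bin
  summaries come with a Kendall-tau trend index.
* **Continuous:** per (gene, drug), the unbinned copy number against the
  transformed response — Pearson, Spearman, and Kendall tau-b
  (tie-adjusted, since screening values tie after rounding) plus OLS and
  Huber-robust (k = 1.345, IRLS to 1e-8, ≤ 50 iterations) linear fits.
  Records with constant copy number or under 3 pairs are not-evaluable.

## Sensitivity maps

Each evaluable SNV comparison becomes a signed score: the reciprocal of
the Welch t p-value (the other two tests feed screening, not maps),
signed +1 when the mutation is sensitizing — lower mutated-group mean for
EC50/IC50, higher for AUC — and −1 otherwise, 0 on an exact tie. For LFC
the convention is that a lower fold-change (stronger kill) is more
sensitive; this is a convention, not a derivation, and is configurable.
The p-value is floored at 1e-300 so scores stay finite. CNV maps use the
Pearson correlation per cell instead. Rows and columns are ordered by
complete-linkage hierarchical clustering on Euclidean distances; missing
cells are imputed as 0 for clustering only and exported as `NA`.
Reciprocal scores are heavy-tailed, so rendering clips |score| at 1000
for color mapping only — stored values are never clipped.

## The synthetic cohort generator

The generator emulates the structure the analysis assumes, and its
defaults are the study conditions for every calibration and recovery
check in the package:

| quantity | model | default |
|---|---|---|
| AUC | Normal truncated at 0 | mean 1.0, sd 0.15 |
| EC50 / IC50 | lognormal | meanlog 0.5, sdlog 1.0 |
| LFC | Normal | mean 0, sd 1 |
| CNV | Normal truncated at 0 + amplifications | mean 1, sd 0.15; p_amp 0.01, amp ~ Uniform(2, 6) |
| SNVs | independent Bernoulli per gene | frequencies log-uniform in [0.05, 0.3] |

The EC50 location/scale (median ≈ 1.6 concentration units, spread about
two orders of magnitude) reflects a multi-step dilution screen topping
out near 10 µM; driver-like mutation frequencies of 5–30% reflect the
elevated mutation rates of driver genes. Planted SNV effects are additive
on the analysis scale — raw for AUC/LFC, log for EC50 — so an effect of
size δ shifts the mutated group by δ pooled SDs and recovery rates can be
checked against the t-test power function; planted CNV effects add
β·(CNV − 1). Everything is deterministic given the spec's single seed.

What the generator deliberately omits: co-mutation structure between
genes, chromosome/segment structure in CNVs, dose-response curve
simulation (AUC/EC50 are drawn, not fit), and drug-drug response
correlations. Passing recovery tests therefore shows the pipeline's
statistics behave as designed under the stated models — not that real
screening data satisfy those models.

## Problem sizes used in the checks

The packaged checks use cohorts of 200–2000 samples, null calibration
with 5000 replicates at n = 50/50, λ-recovery with 100 replicates of
n = 500 pools, and end-to-end recovery with 200 replicates of n = 300
cohorts (δ = 1.5, mutation frequency 0.3) — sizes chosen to estimate the
rates in question to about a percentage point while keeping a full run
in well under a minute on one core.

## Worked example

The bundled `gdsc2_brca_ic50_example()` table carries six published
gene–drug comparisons (GDSC2 breast-cancer IC50 screen) with their three
p-values and group sizes. Applying the rules:

```{r}
ex <- gdsc2_brca_ic50_example()
comp <- data.frame(target = ex$gene, drug = ex$drug, measure = "IC50",
                   n_mut = ex$n_mut, n_unmut = ex$n_unmut,
                   mean_mut = NA_real_, mean_unmut = NA_real_,
                   p_t = ex$p_t, p_w = ex$p_w, p_m = ex$p_m,
                   evaluable = TRUE)
call_biomarkers(comp, screening_rule("strict"))$gene
call_biomarkers(comp, screening_rule("relaxed"))$gene
```

The strict rule keeps ERBB2 (all three p < 0.05) and PIK3CA (p_m =
0.009 < 0.01); the relaxed rule admits all six.

## Known limitations

* The raw-threshold consensus rule controls no family-wise error rate;
  with ~30 genes × ~10 drugs per panel, a handful of null strict calls
  per panel is expected. The optional Benjamini-Hochberg flag on the
  screening report is a deviation from the consensus design and is off
  by default.
* The KS normality p-value is anti-conservative (see above).
* The uncorrected median test is liberal at moderate n (see above).
* Whether group tests should run on transformed or raw values is
  genuinely ambiguous in practice; the default is transformed (the
  transforms exist to serve the t-test), with `transform_values = FALSE`
  exposing the raw-scale alternative. For the two rank tests the choice
  is immaterial — both transforms are strictly monotone, so ranks are
  invariant.
* Sample joining across matrices is by exact identifier string; samples
  missing from any required input are dropped with a logged count.
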