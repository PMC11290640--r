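Package: driverscreen
Title: Driver-Mutation Biomarker Screening for Cell-Line Drug Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A screening pipeline relating driver-gene single nucleotide
    variants (SNVs) and copy number variants (CNVs) of cancer cell lines to
    drug-response measures (AUC, EC50, IC50, LFC). Provides measure-specific
    normalization via Box-Cox and Yeo-Johnson power transforms with
    Kolmogorov-Smirnov normality assessment, three-test group comparisons
    (Welch t, Mann-Whitney-Wilcoxon, Brown-Mood median) with a consensus
    p-value biomarker-calling rule, copy-number binning and correlation
    analyses with linear and robust fits, hierarchically clustered gene-drug
    sensitivity maps based on signed reciprocal significance scores, and a
    synthetic-cohort generator with planted gene-drug effects for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    car,
    optparse
Config/testthat/edition: 3
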