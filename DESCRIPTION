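Package: trscore
Title: Transcriptional and Genotypic Risk Scores Under a Liability-Threshold Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cohorts in which disease liability is mediated by the
    expression of eQTL-regulated genes under a liability-threshold model,
    and compares two individual-level predictors: the genotypic risk score
    (GRS, an unweighted risk-allele count) and the transcriptional risk
    score (TRS, the sum of expression z-scores polarized so that higher
    values always indicate higher risk). Provides per-locus eQTL scans,
    risk-allele and polarity estimation, Mann-Whitney AUC and ROC
    evaluation with paired-bootstrap confidence intervals, per-locus
    allelic odds ratios, a replicate-level experiment runner, and tidy
    TSV import/export for external genotype and expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
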