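#' Export a cohort to TSV files
#'
#' Writes four files into `dir`: `genotypes.tsv` and `expression.tsv`
#' (individuals as rows, an `iid` first column, loci as header columns),
#' `phenotype.tsv` (`iid`, `liability`, `disease` as 0/1), and `truth.tsv`
#' (`locus`, `maf`, `beta`, `eqtl_sign`, `weight`, `direction`). Floating
#' point values are printed with 6 significant digits; rows are in
#' individual-index order.
#'
#' @param cohort A `trs_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geno <- dplyr::bind_cols(tibble(iid = cohort$iid),
                           as_tibble(cohort$genotypes))
  expr <- dplyr::bind_cols(tibble(iid = cohort$iid),
                           as_tibble(signif6(cohort$expression)))
  pheno <- tibble(iid = cohort$iid,
                  liability = signif6(cohort$liability),
                  disease = as.integer(cohort$disease))
  truth <- dplyr::mutate(cohort$truth,
                         dplyr::across(dplyr::where(is.double), signif6))
  readr::write_tsv(geno, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(pheno, file.path(dir, "phenotype.tsv"))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

signif6 <- function(x) signif(x, 6)

#' Export an eQTL scan to TSV
#'
#' Columns: `locus`, `slope`, `se`, `r2`, `eqtl_sign`, `risk_allele`,
#' `polarity`.
#'
#' @param scan A `trs_scan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  out <- dplyr::select(as_tibble(scan), "locus", "slope", "se", "r2",
                       "eqtl_sign", "risk_allele", "polarity")
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.double), signif6))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Export risk scores to TSV plus a JSON sidecar
#'
#' The TSV has columns `iid`, `grs`, `trs`; the sidecar (same path with
#' `.json` appended) records `polarity_source`, `n_loci_used`, and a content
#' hash of the generating config when available.
#'
#' @param scores A `trs_scores`.
#' @param path Output TSV path.
#' @param config Optional `architecture_config` to hash into the sidecar.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, config = NULL) {
  out <- dplyr::mutate(as_tibble(scores), trs = signif6(.data$trs))
  readr::write_tsv(out, path)
  sidecar <- list(
    polarity_source = attr(scores, "polarity_source"),
    n_loci_used = attr(scores, "n_loci_used"),
    config_hash = if (!is.null(config)) rlang::hash(config) else NULL
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Export an evaluation report
#'
#' Writes the scalar fields as JSON (`report.json`), the ROC curves as
#' two-column TSVs (`roc_grs.tsv`, `roc_trs.tsv` with `fpr`, `tpr`), and the
#' per-locus odds ratios as `odds_ratios.tsv` (`locus`, `odds_ratio`).
#'
#' @param evaluation A `trs_evaluation`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(evaluation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- glance(evaluation)
  jsonlite::write_json(as.list(scalars), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(
    dplyr::mutate(evaluation$roc_grs[c("fpr", "tpr")],
                  dplyr::across(dplyr::everything(), signif6)),
    file.path(dir, "roc_grs.tsv"))
  readr::write_tsv(
    dplyr::mutate(evaluation$roc_trs[c("fpr", "tpr")],
                  dplyr::across(dplyr::everything(), signif6)),
    file.path(dir, "roc_trs.tsv"))
  readr::write_tsv(
    dplyr::mutate(evaluation$or_per_locus, odds_ratio = signif6(.data$odds_ratio)),
    file.path(dir, "odds_ratios.tsv"))
  invisible(dir)
}

#' Read genotype, expression, and phenotype TSVs for scoring
#'
#' Reads externally supplied matrices in the package's TSV dialect (see
#' [write_cohort()]), validates them, and aligns all rows by `iid` to the
#' genotype file's order. Dosages must be 0, 1, or 2; violations are
#' reported with their file line number (header = line 1).
#'
#' @param genotype_path,expression_path,phenotype_path TSV file paths.
#' @return A list with `genotypes` (integer matrix), `expression` (numeric
#'   matrix), `phenotype` (tibble `iid`, `liability`, `disease`), and `iid`.
#' @export
read_matrices <- function(genotype_path, expression_path, phenotype_path) {
  geno <- readr::read_tsv(genotype_path, show_col_types = FALSE,
                          progress = FALSE)
  expr <- readr::read_tsv(expression_path, show_col_types = FALSE,
                          progress = FALSE)
  pheno <- readr::read_tsv(phenotype_path, show_col_types = FALSE,
                           progress = FALSE)
  for (nm in c("geno", "expr", "pheno")) {
    df <- get(nm)
    if (names(df)[1] != "iid") {
      abort(sprintf("First column of %s must be `iid`.",
                    switch(nm, geno = genotype_path, expr = expression_path,
                           pheno = phenotype_path)),
            class = "trscore_parse_error")
    }
  }
  gm <- as.matrix(geno[-1])
  bad <- which(!(gm %in% c(0, 1, 2)))
  if (length(bad)) {
    row <- (bad[1] - 1) %% nrow(gm) + 1
    abort(sprintf("Dosage out of {0,1,2} in %s at line %d.",
                  genotype_path, row + 1),
          class = "trscore_parse_error")
  }
  storage.mode(gm) <- "integer"
  if (!setequal(geno$iid, expr$iid) || !setequal(geno$iid, pheno$iid)) {
    abort("`iid` sets differ between genotype, expression, and phenotype files.",
          class = "trscore_parse_error")
  }
  em <- as.matrix(expr[match(geno$iid, expr$iid), -1])
  pheno <- pheno[match(geno$iid, pheno$iid), ]
  if (!identical(colnames(gm), colnames(em))) {
    abort("Locus columns differ between genotype and expression files.",
          class = "trscore_parse_error")
  }
  rownames(gm) <- NULL
  rownames(em) <- NULL
  list(genotypes = gm, expression = em, phenotype = pheno, iid = geno$iid)
}

#' Assemble a cohort from externally supplied matrices
#'
#' Wraps the output of [read_matrices()] as a `trs_cohort` (with no
#' generative truth), so the scan/score/evaluate pipeline applies unchanged
#' to user data.
#'
#' @param mats List from [read_matrices()].
#' @return A `trs_cohort` with `truth = NULL`.
#' @export
as_cohort <- function(mats) {
  structure(
    list(
      genotypes = mats$genotypes,
      expression = mats$expression,
      liability = mats$phenotype$liability,
      disease = as.logical(mats$phenotype$disease),
      iid = mats$iid,
      truth = NULL,
      config = NULL
    ),
    class = "trs_cohort"
  )
}
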