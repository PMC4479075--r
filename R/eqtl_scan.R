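#' Per-locus eQTL scan by ordinary least squares
#'
#' Regresses each transcript on its raw dosage (with intercept) and records
#' the slope, its standard error, the squared Pearson correlation, and the
#' slope sign (a numerically zero slope resolves to +1). Monomorphic loci
#' (zero dosage variance) are flagged with a warning; their slope, standard
#' error and r-squared are `NA` and they are excluded from downstream
#' polarity calls.
#'
#' @param genotypes N x M dosage matrix.
#' @param expression N x M expression matrix.
#' @return Tibble with columns `locus`, `slope`, `se`, `r2`, `eqtl_sign`,
#'   `monomorphic`.
#' @export
scan_eqtls <- function(genotypes, expression) {
  n <- nrow(genotypes)
  if (n < 3) abort("Need at least 3 individuals to fit per-locus slopes.",
                   class = "trscore_domain_error")
  if (!all(dim(genotypes) == dim(expression))) {
    abort("`genotypes` and `expression` must have identical dimensions.",
          class = "trscore_domain_error")
  }
  gm <- colMeans(genotypes)
  tm <- colMeans(expression)
  sxx <- colSums(genotypes^2) - n * gm^2
  syy <- colSums(expression^2) - n * tm^2
  sxy <- colSums(genotypes * expression) - n * gm * tm
  mono <- sxx <= 0
  if (any(mono)) {
    warn(sprintf("%d monomorphic locus/loci flagged and excluded: %s",
                 sum(mono),
                 paste(head(colnames(genotypes)[mono], 5), collapse = ", ")))
  }
  slope <- ifelse(mono, NA_real_, sxy / sxx)
  r2 <- ifelse(mono | syy <= 0, NA_real_, sxy^2 / (sxx * syy))
  sse <- syy - ifelse(mono, 0, sxy^2 / sxx)
  se <- ifelse(mono, NA_real_, sqrt(pmax(sse, 0) / ((n - 2) * sxx)))
  tibble(
    locus = colnames(genotypes) %||% locus_ids(ncol(genotypes)),
    slope = slope,
    se = se,
    r2 = r2,
    eqtl_sign = ifelse(mono, NA_real_, ifelse(slope >= 0, 1, -1)),
    monomorphic = mono
  )
}

#' Call the risk allele at each locus from case/control dosage means
#'
#' The risk allele is the counted allele if mean dosage among cases exceeds
#' the mean among controls, otherwise the other allele. Exact equality
#' resolves to the counted allele (with a message).
#'
#' @param genotypes N x M dosage matrix.
#' @param disease Logical case indicator of length N with both classes
#'   present.
#' @return Character vector of length M with values `"counted"` / `"other"`.
#' @export
determine_risk_alleles <- function(genotypes, disease) {
  check_two_classes(disease)
  diff <- colMeans(genotypes[disease, , drop = FALSE]) -
    colMeans(genotypes[!disease, , drop = FALSE])
  if (any(diff == 0)) {
    inform(sprintf(
      "Tied case/control dosage means at %d locus/loci; resolved to the counted allele.",
      sum(diff == 0)))
  }
  ifelse(diff >= 0, "counted", "other")
}

check_two_classes <- function(disease) {
  if (!any(disease) || all(disease)) {
    abort("`disease` must contain both cases and controls.",
          class = "trscore_domain_error")
  }
  invisible(disease)
}

#' Polarize expression relative to disease risk
#'
#' Polarity is +1 when the high-risk allele increases expression and -1 when
#' it decreases expression: `polarity = eqtl_sign` when the risk allele is
#' the counted allele and `-eqtl_sign` otherwise. With polarity applied,
#' higher polarized expression always means higher genetic risk.
#'
#' @param scan Tibble from [scan_eqtls()] with a `risk_allele` column added
#'   (see [determine_risk_alleles()]).
#' @return `scan` with a `polarity` column (`NA` for monomorphic loci).
#' @export
estimate_polarity <- function(scan) {
  if (!"risk_allele" %in% names(scan)) {
    abort("`scan` needs a `risk_allele` column; run determine_risk_alleles().",
          class = "trscore_domain_error")
  }
  dplyr::mutate(
    scan,
    polarity = dplyr::if_else(
      .data$monomorphic, NA_real_,
      dplyr::if_else(.data$risk_allele == "counted",
                     .data$eqtl_sign, -.data$eqtl_sign))
  )
}

#' Full eQTL scan of a cohort: slopes, risk alleles, polarity
#'
#' Runs [scan_eqtls()], [determine_risk_alleles()] and [estimate_polarity()]
#' on a simulated cohort. With `polarity_source = "oracle"` the orientation
#' columns (`eqtl_sign`, `risk_allele`, `polarity`) are taken from the
#' simulator's ground truth instead of being estimated — useful for
#' separating estimation error from scoring behaviour — while the slope,
#' standard error and r-squared remain estimated from the data.
#'
#' @param cohort A `trs_cohort`.
#' @param polarity_source `"estimated"` (default) or `"oracle"`.
#' @return A `trs_scan` tibble: `locus`, `slope`, `se`, `r2`, `eqtl_sign`,
#'   `monomorphic`, `risk_allele`, `polarity`, with attribute
#'   `polarity_source`.
#' @export
eqtl_scan <- function(cohort, polarity_source = c("estimated", "oracle")) {
  polarity_source <- match.arg(polarity_source)
  scan <- scan_eqtls(cohort$genotypes, cohort$expression)
  if (polarity_source == "estimated") {
    scan$risk_allele <- determine_risk_alleles(cohort$genotypes, cohort$disease)
    scan <- estimate_polarity(scan)
  } else {
    truth <- cohort$truth
    scan$eqtl_sign <- truth$eqtl_sign
    scan$risk_allele <- ifelse(truth$eqtl_sign * truth$direction > 0,
                               "counted", "other")
    scan$polarity <- truth$direction
  }
  attr(scan, "polarity_source") <- polarity_source
  class(scan) <- c("trs_scan", class(scan))
  scan
}
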