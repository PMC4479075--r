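#' Genotypic risk score: unweighted risk-allele count
#'
#' Per individual, the number of risk alleles summed over loci: the dosage
#' itself where the risk allele is the counted allele, `2 - dosage` where it
#' is the other allele. Ranges over `0 .. 2 * n_loci`.
#'
#' @param genotypes N x M dosage matrix.
#' @param risk_alleles Character vector (`"counted"`/`"other"`), one per
#'   locus; `NA` anywhere is an error.
#' @return Integer vector of length N.
#' @export
compute_grs <- function(genotypes, risk_alleles) {
  if (length(risk_alleles) != ncol(genotypes) || anyNA(risk_alleles)) {
    abort("Need a non-missing risk-allele orientation for every locus.",
          class = "trscore_domain_error")
  }
  flip <- risk_alleles == "other"
  grs <- rowSums(genotypes[, !flip, drop = FALSE]) +
    (2L * sum(flip) - rowSums(genotypes[, flip, drop = FALSE]))
  as.integer(grs)
}

#' Column-wise expression z-scores
#'
#' Standardizes each transcript to sample mean 0 and sample standard
#' deviation 1 (denominator N - 1), over the full cohort.
#'
#' @param expression N x M expression matrix, N >= 2.
#' @return Numeric z-score matrix of the same dimensions.
#' @export
standardize_expression <- function(expression) {
  if (nrow(expression) < 2) {
    abort("Need at least 2 individuals to standardize.",
          class = "trscore_domain_error")
  }
  sds <- apply(expression, 2L, sd)
  if (any(sds == 0)) {
    bad <- (colnames(expression) %||% locus_ids(ncol(expression)))[sds == 0]
    abort(sprintf("Zero-variance expression column(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "trscore_domain_error")
  }
  z <- scale(expression)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Transcriptional risk score: polarized z-score sum
#'
#' Per individual, the sum over loci of the expression z-score multiplied by
#' the locus's +/-1 polarity, so that higher TRS always means higher
#' transcriptionally inferred risk. Depends only on expression and polarity,
#' never on how genotypes are coded.
#'
#' @param z Z-score matrix from [standardize_expression()].
#' @param polarity Vector of +/-1, one per column of `z`.
#' @return Numeric vector of length `nrow(z)`.
#' @export
compute_trs <- function(z, polarity) {
  if (length(polarity) != ncol(z)) {
    abort("`polarity` must have one entry per expression column.",
          class = "trscore_domain_error")
  }
  if (anyNA(polarity) || !all(polarity %in% c(-1, 1))) {
    abort("`polarity` entries must be +1 or -1.",
          class = "trscore_domain_error")
  }
  drop(z %*% polarity)
}

#' Compute GRS and TRS for every individual in a cohort
#'
#' Loci flagged monomorphic or with undefined polarity are excluded from
#' both scores symmetrically; `n_loci_used` records how many remain.
#'
#' @param cohort A `trs_cohort`.
#' @param scan A `trs_scan` from [eqtl_scan()] (any polarity source).
#' @return A `trs_scores` tibble with columns `iid`, `grs`, `trs` and
#'   attributes `polarity_used` (named +/-1 vector), `polarity_source`,
#'   `risk_alleles`, `n_loci_used`.
#' @examples
#' cohort <- simulate_cohort(architecture_config(n_individuals = 300,
#'                                               n_loci = 8, seed = 7))
#' scores <- compute_risk_scores(cohort, eqtl_scan(cohort))
#' head(scores)
#' @export
compute_risk_scores <- function(cohort, scan) {
  keep <- !scan$monomorphic & !is.na(scan$polarity)
  if (!any(keep)) abort("No usable loci after exclusions.",
                        class = "trscore_domain_error")
  g <- cohort$genotypes[, keep, drop = FALSE]
  e <- cohort$expression[, keep, drop = FALSE]
  scores <- tibble(
    iid = cohort$iid,
    grs = compute_grs(g, scan$risk_allele[keep]),
    trs = compute_trs(standardize_expression(e), scan$polarity[keep])
  )
  attr(scores, "polarity_used") <- setNames(scan$polarity[keep],
                                            scan$locus[keep])
  attr(scores, "polarity_source") <- attr(scan, "polarity_source") %||%
    "estimated"
  attr(scores, "risk_alleles") <- setNames(scan$risk_allele[keep],
                                           scan$locus[keep])
  attr(scores, "n_loci_used") <- sum(keep)
  class(scores) <- c("trs_scores", class(scores))
  scores
}
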