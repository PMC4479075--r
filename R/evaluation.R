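#' Mann-Whitney area under the ROC curve
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted half — computed from midranks, and exactly
#' equal to the trapezoidal area under the full ROC curve.
#'
#' @param score Numeric score vector (higher = predicted higher risk).
#' @param disease Logical case indicator with both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)) # 0.75
#' @export
auc <- function(score, disease) {
  check_two_classes(disease)
  n1 <- sum(disease)
  n0 <- length(disease) - n1
  r <- data.table::frank(score, ties.method = "average")
  (sum(r[disease]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve over observed score thresholds
#'
#' Sweeps thresholds over the unique observed scores in descending order
#' (predicting "case" for score >= threshold), yielding one point per
#' threshold plus the (0,0) anchor. The trapezoidal area under the curve
#' equals [auc()].
#'
#' @inheritParams auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0,0) to (1,1).
#' @export
roc_curve <- function(score, disease) {
  check_two_classes(disease)
  n1 <- sum(disease)
  n0 <- length(disease) - n1
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  d <- disease[ord]
  last <- cumsum(rle(s)$lengths) # final index of each distinct threshold
  tp <- cumsum(d)[last]
  fp <- cumsum(!d)[last]
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
}

#' AUC difference with a paired percentile bootstrap
#'
#' `delta = auc(score_a) - auc(score_b)` on the full data, with a percentile
#' confidence interval from paired bootstrap resamples of individuals (both
#' scores resampled with the same indices). Degenerate resamples with a
#' single outcome class are redrawn.
#'
#' @param score_a,score_b Numeric score vectors on the same individuals.
#' @param disease Logical case indicator.
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `delta`, `conf_low`, `conf_high`, `n_boot`.
#' @export
auc_difference <- function(score_a, score_b, disease, n_boot = 1000,
                           conf_level = 0.95) {
  check_two_classes(disease)
  if (n_boot < 100) abort("`n_boot` must be >= 100.",
                          class = "trscore_domain_error")
  n <- length(disease)
  deltas <- vapply(seq_len(n_boot), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      d <- disease[idx]
      if (any(d) && !all(d)) break
    }
    auc(score_a[idx], d) - auc(score_b[idx], d)
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- quantile(deltas, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble(
    delta = auc(score_a, disease) - auc(score_b, disease),
    conf_low = ci[1],
    conf_high = ci[2],
    n_boot = as.integer(n_boot)
  )
}

#' Per-locus allelic odds ratios from 2x2 allele-count tables
#'
#' For each locus, alleles (two observations per individual) are
#' cross-tabulated as risk vs non-risk allele by case vs control, and the
#' odds ratio is the cross-product `(a d) / (b c)`. If any cell of a locus's
#' table is zero, 0.5 is added to all four cells of that table
#' (Haldane-Anscombe), guaranteeing a finite positive ratio.
#'
#' @param genotypes N x M dosage matrix (counted-allele dosages).
#' @param disease Logical case indicator.
#' @param risk_alleles `"counted"`/`"other"` per locus.
#' @return Tibble with columns `locus`, `odds_ratio`.
#' @export
allelic_odds_ratios <- function(genotypes, disease, risk_alleles) {
  check_two_classes(disease)
  if (length(risk_alleles) != ncol(genotypes)) {
    abort("Need one risk-allele orientation per locus.",
          class = "trscore_domain_error")
  }
  n1 <- sum(disease)
  n0 <- sum(!disease)
  counted_case <- colSums(genotypes[disease, , drop = FALSE])
  counted_ctrl <- colSums(genotypes[!disease, , drop = FALSE])
  flip <- risk_alleles == "other"
  a <- ifelse(flip, 2 * n1 - counted_case, counted_case)   # case, risk
  b <- 2 * n1 - a                                          # case, non-risk
  c_ <- ifelse(flip, 2 * n0 - counted_ctrl, counted_ctrl)  # control, risk
  d <- 2 * n0 - c_                                         # control, non-risk
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c_ <- c_ + 0.5 * zero; d <- d + 0.5 * zero
  tibble(
    locus = colnames(genotypes) %||% locus_ids(ncol(genotypes)),
    odds_ratio = (a * d) / (b * c_)
  )
}

#' Evaluate GRS and TRS against disease status
#'
#' Reproduces the full comparison for one cohort: Mann-Whitney AUC and ROC
#' curve for each score, the bootstrap confidence interval of their AUC
#' difference, per-locus allelic odds ratios (with their median and
#' second-largest value), the GRS-TRS Pearson correlation, and the number of
#' individuals in the top decile of both scores (ties broken by individual
#' index).
#'
#' @param cohort A `trs_cohort`.
#' @param scores A `trs_scores` from [compute_risk_scores()].
#' @param n_boot Bootstrap resamples for the AUC difference (default 1000).
#' @return A `trs_evaluation` object; see [glance.trs_evaluation()] and
#'   [tidy.trs_evaluation()].
#' @export
evaluate <- function(cohort, scores, n_boot = 1000) {
  disease <- cohort$disease
  risk_alleles <- attr(scores, "risk_alleles")
  keep <- match(names(risk_alleles), colnames(cohort$genotypes))
  ors <- allelic_odds_ratios(cohort$genotypes[, keep, drop = FALSE],
                             disease, unname(risk_alleles))
  or_sorted <- sort(ors$odds_ratio, decreasing = TRUE)
  n <- length(disease)
  n_top <- floor(n / 10)
  top_grs <- order(-scores$grs, seq_len(n))[seq_len(n_top)]
  top_trs <- order(-scores$trs, seq_len(n))[seq_len(n_top)]
  structure(
    list(
      auc_grs = auc(scores$grs, disease),
      auc_trs = auc(scores$trs, disease),
      delta_auc = auc_difference(scores$trs, scores$grs, disease,
                                 n_boot = n_boot),
      roc_grs = roc_curve(scores$grs, disease),
      roc_trs = roc_curve(scores$trs, disease),
      or_per_locus = ors,
      or_median = median(ors$odds_ratio),
      or_second_largest = if (length(or_sorted) >= 2) or_sorted[2] else NA_real_,
      grs_trs_pearson = cor(scores$grs, scores$trs),
      top_decile_overlap = length(intersect(top_grs, top_trs)),
      n_cases = sum(disease),
      n_controls = sum(!disease),
      polarity_source = attr(scores, "polarity_source"),
      n_loci_used = attr(scores, "n_loci_used")
    ),
    class = "trs_evaluation"
  )
}

#' @export
print.trs_evaluation <- function(x, ...) {
  cat("<trs_evaluation>\n")
  cat(sprintf("  AUC: TRS %.4f vs GRS %.4f (delta %.4f, 95%% CI [%.4f, %.4f])\n",
              x$auc_trs, x$auc_grs, x$delta_auc$delta,
              x$delta_auc$conf_low, x$delta_auc$conf_high))
  cat(sprintf("  allelic OR: median %.4f, second largest %.4f\n",
              x$or_median, x$or_second_largest))
  cat(sprintf("  GRS-TRS Pearson r = %.4f; top-decile overlap %d; %d cases / %d controls\n",
              x$grs_trs_pearson, x$top_decile_overlap, x$n_cases, x$n_controls))
  invisible(x)
}

#' One-row summary of an evaluation
#'
#' @param x A `trs_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with the scalar report fields.
#' @export
glance.trs_evaluation <- function(x, ...) {
  tibble(
    auc_grs = x$auc_grs,
    auc_trs = x$auc_trs,
    delta_auc = x$delta_auc$delta,
    delta_auc_low = x$delta_auc$conf_low,
    delta_auc_high = x$delta_auc$conf_high,
    or_median = x$or_median,
    or_second_largest = x$or_second_largest,
    grs_trs_pearson = x$grs_trs_pearson,
    top_decile_overlap = x$top_decile_overlap,
    n_cases = x$n_cases,
    n_controls = x$n_controls,
    n_loci_used = x$n_loci_used,
    polarity_source = x$polarity_source
  )
}

#' Per-locus odds ratios of an evaluation
#'
#' @param x A `trs_evaluation`.
#' @param ... Unused.
#' @return Tibble `locus`, `odds_ratio`.
#' @export
tidy.trs_evaluation <- function(x, ...) x$or_per_locus

#' ROC curves of an evaluation
#'
#' @param object A `trs_evaluation`.
#' @param ... Unused.
#' @return A ggplot of both ROC curves with their AUCs in the legend.
#' @export
autoplot.trs_evaluation <- function(object, ...) {
  curves <- dplyr::bind_rows(
    dplyr::mutate(object$roc_trs,
                  score = sprintf("TRS (AUC %.3f)", object$auc_trs)),
    dplyr::mutate(object$roc_grs,
                  score = sprintf("GRS (AUC %.3f)", object$auc_grs))
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = .data$score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatterplot of GRS against TRS with top-risk individuals highlighted
#'
#' @param scores A `trs_scores` tibble.
#' @param disease Optional logical case indicator used to colour cases.
#' @param top_frac Fraction of top-TRS individuals to highlight
#'   (default 0.01).
#' @return A ggplot.
#' @export
plot_score_scatter <- function(scores, disease = NULL, top_frac = 0.01) {
  df <- tibble(grs = scores$grs, trs = scores$trs)
  df$highlight <- rank(-df$trs, ties.method = "first") <=
    max(1, floor(top_frac * nrow(df)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$grs, .data$trs)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4, colour = "grey40") +
    ggplot2::geom_point(data = df[df$highlight, ],
                        colour = "red", size = 0.6) +
    ggplot2::labs(x = "Genotypic risk score (risk-allele count)",
                  y = "Transcriptional risk score (polarized z-score sum)") +
    ggplot2::theme_minimal()
  p
}

#' Histogram of per-locus allelic odds ratios
#'
#' @param evaluation A `trs_evaluation`.
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_or_distribution <- function(evaluation, bins = 20) {
  ggplot2::ggplot(evaluation$or_per_locus,
                  ggplot2::aes(.data$odds_ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = evaluation$or_median,
                        linetype = "dashed") +
    ggplot2::labs(x = "Allelic odds ratio", y = "Loci") +
    ggplot2::theme_minimal()
}
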