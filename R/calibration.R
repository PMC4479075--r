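#' Calibration diagnostics for a simulated cohort
#'
#' Measures, from the realised data, the quantities the generative model
#' calibrates: the mean over loci of the squared dosage-expression
#' correlation (targets the per-eQTL variance fraction rho^2), the joint
#' regression R-squared of liability on all transcripts (targets the
#' mediated fraction eta^2), and the sample variances of liability and of
#' the expression columns (both target 1).
#'
#' @param cohort A `trs_cohort`.
#' @return One-row tibble: `mean_eqtl_r2`, `transcript_r2`, `var_liability`,
#'   `mean_var_expression`.
#' @export
cohort_calibration <- function(cohort) {
  scan <- scan_eqtls(cohort$genotypes, cohort$expression)
  fit <- stats::lm.fit(cbind(1, cohort$expression), cohort$liability)
  sst <- sum((cohort$liability - mean(cohort$liability))^2)
  tibble(
    mean_eqtl_r2 = mean(scan$r2, na.rm = TRUE),
    transcript_r2 = 1 - sum(fit$residuals^2) / sst,
    var_liability = var(cohort$liability),
    mean_var_expression = mean(apply(cohort$expression, 2L, var))
  )
}
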