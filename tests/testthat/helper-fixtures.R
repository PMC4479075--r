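# Small shared fixtures built in code.

small_config <- function(seed = 1, ...) {
  architecture_config(n_individuals = 2000L, n_loci = 20L, seed = seed, ...)
}

# A locus-truth tibble assembled by hand, for unit tests that need full
# control over signs and weights.
manual_truth <- function(beta, eqtl_sign, weight, direction, env_sd) {
  truth <- tibble::tibble(
    locus = sprintf("locus_%04d", seq_along(beta)),
    beta = beta, eqtl_sign = eqtl_sign, weight = weight, direction = direction
  )
  attr(truth, "env_sd") <- env_sd
  truth
}

# Independent AUC oracle: exhaustive enumeration of case-control pairs,
# ties counted half.
auc_by_enumeration <- function(score, disease) {
  cases <- score[disease]
  controls <- score[!disease]
  total <- 0
  for (x in cases) total <- total + sum(x > controls) + 0.5 * sum(x == controls)
  total / (length(cases) * length(controls))
}

# Trapezoidal area under an ROC tibble.
trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}
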