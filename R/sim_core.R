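#' Draw allele frequencies for every locus
#'
#' Frequencies of the counted allele are drawn independently and uniformly
#' from `[maf_low, maf_high]`. Consumes the current RNG stream; call
#' [set.seed()] (or use [simulate_cohort()], which seeds once and draws all
#' sub-streams in a fixed documented order) for reproducibility.
#'
#' @param config An [architecture_config()].
#' @return Numeric vector of `n_loci` allele frequencies.
#' @export
sample_mafs <- function(config) {
  validate_config(config)
  runif(config$n_loci, config$maf_low, config$maf_high)
}

#' Sample genotype dosages under Hardy-Weinberg proportions
#'
#' Dosage of the counted allele at locus i is Binomial(2, p_i), independent
#' across individuals and loci (no linkage disequilibrium).
#'
#' @param mafs Vector of allele frequencies, each in (0, 1).
#' @param n_individuals Number of individuals to draw.
#' @return Integer matrix (`n_individuals` x `length(mafs)`) with entries in
#'   \{0, 1, 2\}; columns named `locus_0001`, `locus_0002`, ...
#' @export
sample_genotypes <- function(mafs, n_individuals) {
  if (any(mafs <= 0 | mafs >= 1)) {
    abort("All allele frequencies must lie strictly in (0, 1).",
          class = "trscore_domain_error")
  }
  if (n_individuals < 1) {
    abort("`n_individuals` must be >= 1.", class = "trscore_domain_error")
  }
  m <- length(mafs)
  g <- matrix(rbinom(n_individuals * m, 2L, rep(mafs, each = n_individuals)),
              nrow = n_individuals, ncol = m)
  storage.mode(g) <- "integer"
  colnames(g) <- locus_ids(m)
  g
}

locus_ids <- function(m) sprintf("locus_%04d", seq_len(m))

#' Calibrate per-locus effect sizes, weights, and direction signs
#'
#' Fixes the deterministic part of the architecture: every eQTL slope on the
#' standardized-genotype scale is `sqrt(eqtl_var_frac)`, every liability
#' weight is `sqrt(eta^2 / M)` (equal weighting of unit-variance transcripts,
#' so the mediated component has variance eta^2 exactly), and the residual
#' liability standard deviation is `sqrt(1 - eta^2)`. The direction signs are
#' random fair coin flips: `eqtl_sign` says whether the counted allele
#' increases or decreases expression, `direction` whether higher expression
#' raises or lowers liability — the expression-increasing allele can be
#' protective or risk-increasing.
#'
#' @inheritParams sample_mafs
#' @return A tibble with one row per locus and columns `locus`, `beta`,
#'   `eqtl_sign`, `weight`, `direction`, carrying the residual liability SD
#'   as attribute `env_sd`.
#' @export
calibrate_architecture <- function(config) {
  validate_config(config)
  m <- config$n_loci
  eta2 <- mediated_var_frac(config)
  truth <- tibble(
    locus = locus_ids(m),
    beta = sqrt(config$eqtl_var_frac),
    eqtl_sign = sample(c(-1, 1), m, replace = TRUE),
    weight = sqrt(eta2 / m),
    direction = sample(c(-1, 1), m, replace = TRUE)
  )
  attr(truth, "env_sd") <- sqrt(1 - eta2)
  truth
}

#' Simulate expression regulated by cis-eQTLs
#'
#' Each transcript is a linear additive function of its standardized dosage:
#' `T_i = s_i * beta_i * x_i + e_i` with
#' `x_i = (G_i - 2 p_i) / sqrt(2 p_i (1 - p_i))` standardized by the true
#' generative allele frequency, and `e_i ~ Normal(0, 1 - rho^2)`, so every
#' column has population mean 0 and variance 1.
#'
#' @param genotypes Dosage matrix from [sample_genotypes()].
#' @param mafs True allele frequencies used to generate `genotypes`.
#' @param truth Locus tibble from [calibrate_architecture()].
#' @return Numeric expression matrix with the same dimensions and column
#'   names as `genotypes`.
#' @export
simulate_expression <- function(genotypes, mafs, truth) {
  m <- ncol(genotypes)
  if (length(mafs) != m || nrow(truth) != m) {
    abort("`genotypes`, `mafs`, and `truth` disagree on the number of loci.",
          class = "trscore_domain_error")
  }
  n <- nrow(genotypes)
  x <- scale_dosage(genotypes, mafs)
  noise_sd <- sqrt(1 - truth$beta^2)
  expr <- sweep(x, 2L, truth$eqtl_sign * truth$beta, `*`) +
    matrix(rnorm(n * m, sd = rep(noise_sd, each = n)), nrow = n, ncol = m)
  colnames(expr) <- colnames(genotypes)
  expr
}

# Standardize dosages by the true generative frequency (population moments).
scale_dosage <- function(genotypes, mafs) {
  ctr <- 2 * mafs
  scl <- sqrt(2 * mafs * (1 - mafs))
  out <- scale(genotypes, center = ctr, scale = scl)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Simulate liability mediated by transcript abundance
#'
#' `L = sum_i d_i * w_i * T_i + eps`, `eps ~ Normal(0, env_sd^2)`. With the
#' calibrated equal weights the population variance of L is 1 and the
#' transcript-mediated share is eta^2.
#'
#' @param expression Expression matrix from [simulate_expression()].
#' @param truth Locus tibble from [calibrate_architecture()].
#' @return Numeric liability vector of length `nrow(expression)`.
#' @export
simulate_liability <- function(expression, truth) {
  if (ncol(expression) != nrow(truth)) {
    abort("`expression` and `truth` disagree on the number of loci.",
          class = "trscore_domain_error")
  }
  env_sd <- attr(truth, "env_sd")
  drop(expression %*% (truth$direction * truth$weight)) +
    rnorm(nrow(expression), sd = env_sd)
}

#' Assign disease by liability threshold
#'
#' Deterministic threshold model: exactly `floor(prevalence * N)` individuals
#' — those with the largest liability — are labelled diseased. Ties are
#' broken by ascending individual index.
#'
#' @param liability Numeric liability vector.
#' @param prevalence Disease prevalence K in (0, 1).
#' @return Logical vector: `TRUE` for cases.
#' @export
assign_disease <- function(liability, prevalence) {
  n <- length(liability)
  n_cases <- floor(prevalence * n)
  if (prevalence <= 0 || prevalence >= 1 || n_cases < 1) {
    abort("`prevalence` must lie in (0, 1) with floor(prevalence * N) >= 1.",
          class = "trscore_domain_error")
  }
  ord <- order(-liability, seq_len(n))
  disease <- logical(n)
  disease[ord[seq_len(n_cases)]] <- TRUE
  disease
}

#' Simulate a complete cohort
#'
#' Orchestrates the full generative model with a single seeded RNG stream,
#' drawing sub-streams in a fixed order: allele frequencies, direction signs,
#' genotypes, expression noise, liability noise. Identical configs give
#' bit-identical cohorts.
#'
#' @inheritParams sample_mafs
#' @return A `trs_cohort`: list with elements `genotypes` (N x M integer),
#'   `expression` (N x M numeric), `liability` (length N), `disease`
#'   (logical, length N), `iid` (individual identifiers), `truth` (per-locus
#'   tibble including `maf`), and `config`.
#' @examples
#' cohort <- simulate_cohort(architecture_config(n_individuals = 200,
#'                                               n_loci = 5, seed = 42))
#' cohort
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  mafs <- sample_mafs(config)
  truth <- calibrate_architecture(config)
  genotypes <- sample_genotypes(mafs, config$n_individuals)
  expression <- simulate_expression(genotypes, mafs, truth)
  liability <- simulate_liability(expression, truth)
  disease <- assign_disease(liability, config$prevalence)
  truth <- dplyr::mutate(truth, maf = mafs, .after = "locus")
  attr(truth, "env_sd") <- sqrt(1 - mediated_var_frac(config))
  structure(
    list(
      genotypes = genotypes,
      expression = expression,
      liability = liability,
      disease = disease,
      iid = sprintf("ind_%07d", seq_len(config$n_individuals)),
      truth = truth,
      config = config
    ),
    class = "trs_cohort"
  )
}

#' @export
print.trs_cohort <- function(x, ...) {
  cat("<trs_cohort>\n")
  cat(sprintf("  %d individuals x %d loci; %d cases (prevalence %g)\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(x$disease),
              x$config$prevalence))
  cat(sprintf("  rho^2 = %g, mediated eta^2 = %g, seed = %d\n",
              x$config$eqtl_var_frac, mediated_var_frac(x$config),
              x$config$seed))
  invisible(x)
}

#' Tidy a simulated cohort's per-individual phenotype table
#'
#' @param x A `trs_cohort`.
#' @param ... Unused.
#' @return Tibble with columns `iid`, `liability`, `disease`.
#' @export
tidy.trs_cohort <- function(x, ...) {
  tibble(iid = x$iid, liability = x$liability, disease = x$disease)
}
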