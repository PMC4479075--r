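#' Genetic architecture of a simulated cohort
#'
#' Defines every generative parameter of the genotype -> expression ->
#' liability -> disease model. The defaults are the reference experiment:
#' 100,000 individuals, 100 genes each regulated by a single cis-eQTL that
#' explains 25% of its transcript's variance, the 100 transcripts jointly
#' carrying half of the liability variance, and disease assigned to the top
#' decile of liability (10% prevalence).
#'
#' @param n_individuals Cohort size N (>= 2).
#' @param n_loci Number of gene/eQTL pairs M (>= 1).
#' @param eqtl_var_frac Fraction rho^2 of each transcript's variance explained
#'   by its regulating variant, in (0, 1].
#' @param transcript_var_frac Fraction eta^2 of liability variance carried by
#'   the transcript-mediated component, in (0, 1]. When
#'   `variance_anchor = "genotype"` this value is instead the *genotypic*
#'   fraction of liability variance, and the mediated fraction is derived as
#'   `transcript_var_frac / eqtl_var_frac` (which must not exceed 1).
#' @param prevalence Disease prevalence K in (0, 1); exactly
#'   `floor(K * N)` individuals are labelled diseased.
#' @param maf_low,maf_high Bounds of the uniform allele-frequency
#'   distribution, with `0 < maf_low <= maf_high <= 0.5`.
#' @param weight_scheme Per-transcript liability weighting; only `"equal"`
#'   is defined.
#' @param variance_anchor Whether `transcript_var_frac` anchors the
#'   transcript-mediated (`"transcript"`, default) or the genotypic
#'   (`"genotype"`) share of liability variance.
#' @param seed Integer seed; [simulate_cohort()] is a pure function of the
#'   config, so identical configs give bit-identical cohorts.
#'
#' @return An object of class `architecture_config` (a validated named list).
#' @seealso [simulate_cohort()]
#' @examples
#' cfg <- architecture_config(n_individuals = 500, n_loci = 10, seed = 1)
#' cfg
#' @export
architecture_config <- function(n_individuals = 100000L,
                                n_loci = 100L,
                                eqtl_var_frac = 0.25,
                                transcript_var_frac = 0.5,
                                prevalence = 0.1,
                                maf_low = 0.1,
                                maf_high = 0.5,
                                weight_scheme = "equal",
                                variance_anchor = c("transcript", "genotype"),
                                seed = 1L) {
  variance_anchor <- match.arg(variance_anchor)
  cfg <- structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_loci = as.integer(n_loci),
      eqtl_var_frac = as.numeric(eqtl_var_frac),
      transcript_var_frac = as.numeric(transcript_var_frac),
      prevalence = as.numeric(prevalence),
      maf_low = as.numeric(maf_low),
      maf_high = as.numeric(maf_high),
      weight_scheme = weight_scheme,
      variance_anchor = variance_anchor,
      seed = as.integer(seed)
    ),
    class = "architecture_config"
  )
  validate_config(cfg)
}

#' Validate an architecture configuration
#'
#' Checks every invariant of the generative model and returns the config
#' invisibly unchanged, or aborts naming the offending field.
#'
#' @param config An `architecture_config`.
#' @return The config, invisibly validated.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(sprintf("Invalid `%s`: %s", field, msg),
                           class = "trscore_config_error")
  }
  chk(is.finite(config$n_individuals) && config$n_individuals >= 2,
      "n_individuals", "need at least 2 individuals")
  chk(is.finite(config$n_loci) && config$n_loci >= 1,
      "n_loci", "need at least 1 locus")
  chk(config$eqtl_var_frac > 0 && config$eqtl_var_frac <= 1,
      "eqtl_var_frac", "must lie in (0, 1]")
  chk(config$transcript_var_frac > 0 && config$transcript_var_frac <= 1,
      "transcript_var_frac", "must lie in (0, 1]")
  chk(config$prevalence > 0 && config$prevalence < 1,
      "prevalence", "must lie in (0, 1)")
  chk(floor(config$prevalence * config$n_individuals) >= 1,
      "prevalence", "floor(prevalence * n_individuals) must be >= 1")
  chk(config$maf_low > 0, "maf_low", "must be > 0")
  chk(config$maf_high <= 0.5, "maf_high", "must be <= 0.5")
  chk(config$maf_low <= config$maf_high,
      "maf_low", "must not exceed maf_high")
  chk(identical(config$weight_scheme, "equal"),
      "weight_scheme", "only \"equal\" is defined")
  chk(config$variance_anchor %in% c("transcript", "genotype"),
      "variance_anchor", "must be \"transcript\" or \"genotype\"")
  if (identical(config$variance_anchor, "genotype")) {
    chk(config$transcript_var_frac / config$eqtl_var_frac <= 1,
        "transcript_var_frac",
        paste0("a genotypic share of ", config$transcript_var_frac,
               " is unreachable when each eQTL explains ",
               config$eqtl_var_frac, " of its transcript"))
  }
  chk(is.finite(config$seed), "seed", "must be a finite integer")
  invisible(config)
}

# Mediated (transcript-carried) fraction of liability variance implied by the
# config under its variance anchor.
mediated_var_frac <- function(config) {
  switch(config$variance_anchor,
    transcript = config$transcript_var_frac,
    genotype = config$transcript_var_frac / config$eqtl_var_frac
  )
}

#' @export
print.architecture_config <- function(x, ...) {
  cat("<architecture_config>\n")
  cat(sprintf("  N = %d individuals, M = %d loci\n", x$n_individuals, x$n_loci))
  cat(sprintf("  per-eQTL transcript variance rho^2 = %g\n", x$eqtl_var_frac))
  cat(sprintf("  mediated liability variance eta^2 = %g (%s anchor)\n",
              mediated_var_frac(x), x$variance_anchor))
  cat(sprintf("  prevalence K = %g, MAF ~ U(%g, %g), seed = %d\n",
              x$prevalence, x$maf_low, x$maf_high, x$seed))
  invisible(x)
}
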