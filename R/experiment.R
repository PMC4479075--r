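#' Specify a replicate-level experiment
#'
#' A replicate r (1-based) is simulated with seed `base_seed + r`, scanned,
#' scored, and evaluated; the architecture is shared across replicates.
#'
#' @param architecture An [architecture_config()] (its own `seed` field is
#'   ignored in favour of the replicate seeds).
#' @param n_replicates Number of replicates (>= 1; default 25).
#' @param base_seed Integer base seed (default 0).
#' @param polarity_source `"estimated"` or `"oracle"` polarity for scoring.
#' @param n_boot Bootstrap resamples per replicate for the AUC difference.
#' @param output_dir Optional directory; when given, per-replicate artifacts
#'   and the aggregate table are written there.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(architecture = architecture_config(),
                            n_replicates = 25L,
                            base_seed = 0L,
                            polarity_source = c("estimated", "oracle"),
                            n_boot = 1000L,
                            output_dir = NULL) {
  polarity_source <- match.arg(polarity_source)
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.",
                              class = "trscore_config_error")
  validate_config(architecture)
  structure(
    list(architecture = architecture,
         n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed),
         polarity_source = polarity_source,
         n_boot = as.integer(n_boot),
         output_dir = output_dir),
    class = "experiment_spec"
  )
}

config_keys <- c("n_individuals", "n_loci", "eqtl_var_frac",
                 "transcript_var_frac", "prevalence", "maf_low", "maf_high",
                 "weight_scheme", "variance_anchor", "seed")
spec_keys <- c("n_replicates", "base_seed", "polarity_source", "n_boot",
               "output_dir")

#' Load an experiment specification from a JSON config file and overrides
#'
#' The file is a flat JSON object whose keys are the fields of
#' [architecture_config()] and [experiment_spec()]; unknown keys are
#' rejected by name. Values in `overrides` (e.g. parsed command-line flags)
#' win over file values.
#'
#' @param path Path to a JSON config file, or `NULL` for defaults only.
#' @param overrides Named list of overriding values.
#' @return An `experiment_spec`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file not found: %s", path),
                                  class = "trscore_config_error")
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals <- modifyList(vals, overrides)
  unknown <- setdiff(names(vals), c(config_keys, spec_keys))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "trscore_config_error")
  }
  arch <- do.call(architecture_config, vals[intersect(names(vals), config_keys)])
  do.call(experiment_spec,
          c(list(architecture = arch), vals[intersect(names(vals), spec_keys)]))
}

#' Run one replicate of the pipeline
#'
#' simulate -> scan -> score -> evaluate with a single seed.
#'
#' @param config An [architecture_config()] (seed included).
#' @param polarity_source Polarity mode passed to [eqtl_scan()].
#' @param n_boot Bootstrap resamples for the AUC difference.
#' @return A `trs_evaluation`.
#' @export
run_replicate <- function(config, polarity_source = "estimated",
                          n_boot = 1000) {
  cohort <- simulate_cohort(config)
  scan <- eqtl_scan(cohort, polarity_source = polarity_source)
  scores <- compute_risk_scores(cohort, scan)
  evaluate(cohort, scores, n_boot = n_boot)
}

#' Run a replicated experiment
#'
#' Runs every replicate, collects one [glance()] row per replicate, and
#' summarises means and standard deviations of the headline metrics. When
#' `output_dir` is set, writes `aggregate.tsv` (one row per replicate),
#' `summary.tsv`, and `run_info.json` (resolved config, seeds, config hash,
#' package version).
#'
#' @param spec An [experiment_spec()].
#' @return A list with `replicates` (tibble, one row per replicate, with a
#'   `replicate` and `seed` column) and `summary` (tibble of means/sds).
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  reps <- purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
    cfg <- spec$architecture
    cfg$seed <- spec$base_seed + r
    ev <- run_replicate(cfg, polarity_source = spec$polarity_source,
                        n_boot = spec$n_boot)
    dplyr::bind_cols(tibble(replicate = r, seed = cfg$seed), glance(ev))
  })
  metrics <- c("auc_grs", "auc_trs", "delta_auc", "or_median",
               "grs_trs_pearson")
  summary <- tidyr::pivot_longer(reps[metrics], dplyr::everything(),
                                 names_to = "metric")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value),
                              sd = sd(.data$value),
                              .groups = "drop")
  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_aggregate(reps, summary, spec)
  }
  list(replicates = reps, summary = summary)
}

write_aggregate <- function(reps, summary, spec) {
  num6 <- function(df) dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                                       signif6))
  readr::write_tsv(num6(reps), file.path(spec$output_dir, "aggregate.tsv"))
  readr::write_tsv(num6(summary), file.path(spec$output_dir, "summary.tsv"))
  info <- list(
    architecture = unclass(spec$architecture),
    n_replicates = spec$n_replicates,
    base_seed = spec$base_seed,
    seeds = spec$base_seed + seq_len(spec$n_replicates),
    polarity_source = spec$polarity_source,
    n_boot = spec$n_boot,
    config_hash = rlang::hash(spec$architecture),
    package_version = as.character(utils::packageVersion("trscore"))
  )
  jsonlite::write_json(info, file.path(spec$output_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
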