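test_that("allele frequencies are uniform on the configured interval", {
  cfg <- architecture_config(n_individuals = 100, n_loci = 50,
                             maf_low = 0.3, maf_high = 0.3, seed = 1)
  set.seed(1)
  expect_identical(sample_mafs(cfg), rep(0.3, 50))

  cfg <- architecture_config(n_individuals = 100, n_loci = 10000,
                             maf_low = 0.1, maf_high = 0.5, seed = 1)
  set.seed(1)
  mafs <- sample_mafs(cfg)
  # Uniform(0.1, 0.5): mean 0.3, sd 0.4/sqrt(12)
  se <- 0.4 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(mafs) - 0.3), 4 * se)
  expect_true(all(mafs >= 0.1 & mafs <= 0.5))

  expect_error(architecture_config(maf_low = 0.4, maf_high = 0.2),
               "maf_low")
})

test_that("genotypes follow Hardy-Weinberg proportions and are reproducible", {
  expect_error(sample_genotypes(c(0, 0.5), 10), class = "trscore_domain_error")

  set.seed(2)
  g <- sample_genotypes(rep(0.2, 1), 100000)
  freqs <- tabulate(g + 1L, nbins = 3L) / length(g)
  # exact HW probabilities at p = 0.2: (0.64, 0.32, 0.04)
  expected <- c(0.64, 0.32, 0.04)
  tol <- 4 * sqrt(expected * (1 - expected) / length(g))
  expect_true(all(abs(freqs - expected) < tol))

  set.seed(3)
  g1 <- sample_genotypes(c(0.1, 0.4), 500)
  set.seed(3)
  g2 <- sample_genotypes(c(0.1, 0.4), 500)
  expect_identical(g1, g2)
})

test_that("architecture calibration fixes slopes, weights, and residual SD", {
  cfg <- architecture_config(n_individuals = 100, n_loci = 100,
                             eqtl_var_frac = 0.25, seed = 1)
  set.seed(1)
  truth <- calibrate_architecture(cfg)
  expect_equal(truth$beta, rep(0.5, 100)) # sqrt(0.25)
  expect_true(all(truth$eqtl_sign %in% c(-1, 1)))
  expect_true(all(truth$direction %in% c(-1, 1)))

  cfg <- architecture_config(n_individuals = 100, n_loci = 4,
                             transcript_var_frac = 1, seed = 1)
  set.seed(1)
  truth <- calibrate_architecture(cfg)
  expect_equal(truth$weight, rep(0.5, 4))
  expect_equal(attr(truth, "env_sd"), 0)

  # Monte-Carlo check that mediated + residual liability variance is 1
  cfg <- architecture_config(n_individuals = 100, n_loci = 100,
                             transcript_var_frac = 0.5, seed = 1)
  set.seed(1)
  truth <- calibrate_architecture(cfg)
  expect_equal(truth$weight[1], sqrt(0.5 / 100))
  expect_equal(attr(truth, "env_sd"), sqrt(0.5))
  set.seed(99)
  tmat <- matrix(rnorm(2e5 * 5), ncol = 5)
  w5 <- manual_truth(rep(0.5, 5), rep(1, 5), rep(sqrt(0.5 / 5), 5),
                     sample(c(-1, 1), 5, TRUE), sqrt(0.5))
  l <- simulate_liability(tmat, w5)
  expect_lt(abs(var(l) - 1), 0.02)
})

test_that("expression is linear in standardized dosage with unit variance", {
  cfg <- architecture_config(n_individuals = 5000, n_loci = 10,
                             eqtl_var_frac = 1, seed = 4)
  cohort <- simulate_cohort(cfg)
  # zero-noise limit: expression is exactly the signed standardized dosage
  p <- cohort$truth$maf
  x <- scale(cohort$genotypes, center = 2 * p, scale = sqrt(2 * p * (1 - p)))
  expected <- unname(sweep(x, 2, cohort$truth$eqtl_sign, `*`))
  attributes(expected) <- list(dim = dim(expected))
  expect_equal(unname(cohort$expression), expected, tolerance = 1e-12)
  r2 <- sapply(1:10, function(i) cor(cohort$genotypes[, i],
                                     cohort$expression[, i])^2)
  expect_equal(r2, rep(1, 10), tolerance = 1e-12)

  expect_error(simulate_expression(cohort$genotypes, p[1:3], cohort$truth),
               class = "trscore_domain_error")
})

test_that("liability is the weighted polarized transcript sum plus noise", {
  # single transcript, full mediation, positive direction: L equals T
  tr <- manual_truth(0.5, 1, 1, 1, 0)
  tmat <- matrix(rnorm(50), ncol = 1)
  expect_equal(simulate_liability(tmat, tr), drop(tmat))

  # negating every direction (zero noise) negates the mediated component
  tr2 <- manual_truth(rep(0.5, 3), rep(1, 3), rep(0.4, 3), c(1, -1, 1), 0)
  tr2neg <- manual_truth(rep(0.5, 3), rep(1, 3), rep(0.4, 3), -c(1, -1, 1), 0)
  tmat <- matrix(rnorm(60), ncol = 3)
  expect_equal(simulate_liability(tmat, tr2),
               -simulate_liability(tmat, tr2neg))
})

test_that("disease is assigned to the top liability stratum deterministically", {
  expect_identical(which(assign_disease(c(3, 1, 2, 5), 0.5)), c(1L, 4L))
  expect_error(assign_disease(rnorm(5), 0.1), class = "trscore_domain_error")

  l <- rnorm(1000)
  d <- assign_disease(l, 0.1)
  expect_identical(sum(d), 100L)
  expect_gt(min(l[d]), max(l[!d]))

  # ties broken by ascending index
  expect_identical(which(assign_disease(c(1, 1, 1, 0), 0.5)), c(1L, 2L))
})

test_that("simulate_cohort is reproducible, calibrated, and dimension-consistent", {
  cfg <- small_config(seed = 7)
  cohort <- simulate_cohort(cfg)
  expect_identical(dim(cohort$genotypes), dim(cohort$expression))
  expect_identical(sum(cohort$disease), 200L)
  expect_identical(length(cohort$liability), 2000L)
  expect_true(all(cohort$genotypes %in% 0:2))

  again <- simulate_cohort(cfg)
  expect_identical(cohort$genotypes, again$genotypes)
  expect_identical(cohort$liability, again$liability)

  other <- simulate_cohort(small_config(seed = 8))
  expect_false(identical(cohort$genotypes, other$genotypes))

  expect_lt(abs(mean(apply(cohort$expression, 2, var)) - 1), 0.05)
  expect_lt(abs(var(cohort$liability) - 1), 0.1)
})

test_that("per-locus genotype counts pass a Hardy-Weinberg chi-square screen", {
  cohort <- simulate_cohort(architecture_config(n_individuals = 5000,
                                                n_loci = 200, seed = 11))
  pvals <- sapply(seq_len(200), function(i) {
    p <- cohort$truth$maf[i]
    obs <- tabulate(cohort$genotypes[, i] + 1L, nbins = 3L)
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - 5000 * expected)^2 / (5000 * expected))
    stats::pchisq(stat, df = 2, lower.tail = FALSE)
  })
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("the genotype variance anchor rescales the mediated fraction", {
  cfg <- architecture_config(n_individuals = 1000, n_loci = 10,
                             eqtl_var_frac = 0.25, transcript_var_frac = 0.125,
                             variance_anchor = "genotype", seed = 1)
  expect_equal(trscore:::mediated_var_frac(cfg), 0.5)
  expect_error(architecture_config(eqtl_var_frac = 0.25,
                                   transcript_var_frac = 0.5,
                                   variance_anchor = "genotype"),
               "transcript_var_frac")
})
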