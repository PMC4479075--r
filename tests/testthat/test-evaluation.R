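test_that("Mann-Whitney AUC matches direct pair enumeration on small cases", {
  d <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(auc(c(1, 2, 3, 4), d), 1.0)
  expect_equal(auc(c(1, 3, 2, 4), d), 0.75) # 3 of 4 case-control pairs won
  expect_equal(auc(rep(1, 4), d), 0.5)
  expect_error(auc(1:4, rep(TRUE, 4)), class = "trscore_domain_error")
})

test_that("AUC equals exhaustive pair enumeration on random tied data", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    score <- sample(0:8, n, replace = TRUE) # heavy ties
    d <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(d) || all(d)) next
    expect_identical(auc(score, d), auc_by_enumeration(score, d))
  }
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(16)
  score <- rnorm(300)
  d <- score + rnorm(300) > 0.5
  expect_equal(auc(exp(score), d), auc(score, d))
  expect_equal(auc(-score, d), 1 - auc(score, d))
})

test_that("the ROC curve is anchored, monotone, and integrates to the AUC", {
  d <- c(FALSE, FALSE, TRUE, TRUE)
  roc <- roc_curve(c(1, 2, 3, 4), d)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1)) # perfect separation

  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    score <- sample(0:20, n, replace = TRUE)
    d <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(d) || all(d)) next
    roc <- roc_curve(score, d)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
    expect_equal(trapezoid_area(roc), auc(score, d))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  score <- rnorm(500)
  d <- score + rnorm(500) > 1
  reference <- as.numeric(pROC::auc(pROC::roc(d, score, quiet = TRUE,
                                              direction = "<")))
  expect_equal(auc(score, d), reference)
})

test_that("the paired bootstrap AUC difference behaves as expected", {
  set.seed(19)
  score <- rnorm(400)
  d <- score + rnorm(400) > 1
  same <- auc_difference(score, score, d, n_boot = 200)
  expect_equal(same$delta, 0)
  expect_lte(same$conf_low, 0)
  expect_gte(same$conf_high, 0)

  other <- rnorm(400)
  set.seed(20)
  ab <- auc_difference(score, other, d, n_boot = 150)
  set.seed(20)
  ba <- auc_difference(other, score, d, n_boot = 150)
  expect_equal(ab$delta, -ba$delta)
  expect_error(auc_difference(score, other, d, n_boot = 10),
               class = "trscore_domain_error")
})

test_that("allelic odds ratios match the 2x2 cross-product", {
  # cases: 30 risk / 10 non-risk alleles; controls: 10 risk / 30 non-risk
  g <- matrix(c(rep(2L, 10), rep(1L, 10), rep(1L, 10), rep(0L, 10)), ncol = 1)
  d <- c(rep(TRUE, 20), rep(FALSE, 20))
  expect_equal(allelic_odds_ratios(g, d, "counted")$odds_ratio, 9.0)
  # orientation flip inverts the (uncorrected) odds ratio
  expect_equal(allelic_odds_ratios(g, d, "other")$odds_ratio, 1 / 9.0)

  # identical case and control allele frequencies: OR = 1
  g0 <- matrix(rep(c(0L, 1L, 2L), 4), ncol = 1)
  d0 <- rep(c(TRUE, FALSE), each = 6)
  expect_equal(allelic_odds_ratios(g0, d0, "counted")$odds_ratio, 1.0)

  # zero cell: Haldane-Anscombe keeps the ratio finite and positive
  gz <- matrix(c(rep(2L, 5), rep(0L, 5)), ncol = 1)
  dz <- c(rep(TRUE, 5), rep(FALSE, 5))
  or <- allelic_odds_ratios(gz, dz, "counted")$odds_ratio
  expect_true(is.finite(or) && or > 0)
  expect_equal(or, (10.5 * 10.5) / (0.5 * 0.5))
})

test_that("OR inversion under orientation flip holds on simulated data", {
  cohort <- simulate_cohort(small_config(seed = 21))
  ra <- determine_risk_alleles(cohort$genotypes, cohort$disease)
  flipped <- ifelse(ra == "counted", "other", "counted")
  or1 <- allelic_odds_ratios(cohort$genotypes, cohort$disease, ra)$odds_ratio
  or2 <- allelic_odds_ratios(cohort$genotypes, cohort$disease,
                             flipped)$odds_ratio
  expect_equal(or2, 1 / or1, tolerance = 1e-12)
})

test_that("evaluate() assembles a coherent report", {
  cohort <- simulate_cohort(small_config(seed = 22))
  scores <- compute_risk_scores(cohort, eqtl_scan(cohort))
  ev <- evaluate(cohort, scores, n_boot = 120)

  # liability defines disease, so it is a perfect score (sanity ceiling)
  expect_equal(auc(cohort$liability, cohort$disease), 1.0)

  expect_true(ev$auc_grs >= 0 && ev$auc_grs <= 1)
  expect_true(ev$auc_trs >= 0 && ev$auc_trs <= 1)
  expect_equal(ev$delta_auc$delta, ev$auc_trs - ev$auc_grs)
  expect_equal(trapezoid_area(ev$roc_trs), ev$auc_trs)
  expect_identical(nrow(ev$or_per_locus), 20L)
  expect_equal(ev$or_median, median(ev$or_per_locus$odds_ratio))
  expect_equal(ev$or_second_largest,
               sort(ev$or_per_locus$odds_ratio, decreasing = TRUE)[2])
  expect_identical(ev$n_cases, 200L)
  expect_identical(ev$n_controls, 1800L)
  expect_true(ev$top_decile_overlap >= 0 && ev$top_decile_overlap <= 200)

  gl <- glance(ev)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$auc_trs, ev$auc_trs)
  expect_identical(nrow(tidy(ev)), 20L)

  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
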