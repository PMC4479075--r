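---
title: "Transcriptional risk scores: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional risk scores: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trscore)
```

## The generative model

`trscore` simulates a disease whose incidence is driven by the expression of
M genes, each regulated by a single cis-eQTL, and compares two
individual-level predictors on the simulated cohorts: the genotypic risk
score (GRS, an oriented allele count) and the transcriptional risk score
(TRS, a polarized expression z-score sum).

The model has four layers, each calibrated so its scale is known exactly:

1. **Genotypes.** Allele frequencies are drawn uniformly on
   `[maf_low, maf_high]` (default 0.1–0.5), and dosages of the counted
   allele are Binomial(2, p) — Hardy–Weinberg proportions, no linkage
   disequilibrium, no population structure.
2. **Expression.** Transcript i is linear in its standardized dosage
   `x_i = (G_i − 2p_i) / √(2 p_i (1 − p_i))`:
   `T_i = s_i β x_i + e_i`, with `β = √ρ²`, `e_i ~ N(0, 1 − ρ²)`, and
   `s_i = ±1` a fair coin flip. Every transcript has population mean 0 and
   variance 1, and its eQTL explains exactly ρ² of that variance (default
   0.25).
3. **Liability.** `L = Σ_i d_i w_i T_i + ε` with equal weights
   `w_i = √(η²/M)`, direction signs `d_i = ±1` fair coin flips, and
   `ε ~ N(0, 1 − η²)`. L has population variance 1 and the transcripts
   jointly carry η² of it (default 0.5). Because `s_i` and `d_i` are
   independent, the allele that increases expression is risk-increasing at
   about half the loci and protective at the other half.
4. **Disease.** The `floor(K·N)` individuals with the largest liability are
   cases (default K = 0.1, N = 100,000) — a deterministic threshold model,
   with liability ties broken by ascending individual index.

### Why η² anchors the *mediated* variance

The headline "half the risk" of the default architecture is implemented as
the transcript-mediated fraction of liability variance (η² = 0.5), not as
narrow-sense genotypic heritability. In a fully expression-mediated model
the genotypes can explain at most ρ² of whatever the transcripts explain,
so with ρ² = 0.25 a genotypic fraction of 0.5 is algebraically unreachable;
under the mediated reading the genotypic share is ρ²·η² = 12.5%, which is
also what makes the per-locus allelic odds ratios land near 1.1 (see
below). For users who want to anchor the genotypic share instead,
`architecture_config(variance_anchor = "genotype")` reinterprets
`transcript_var_frac` as the genotypic fraction and derives the mediated
fraction as `transcript_var_frac / eqtl_var_frac`, validating that it does
not exceed 1.

### Expected magnitudes

With the defaults, the per-allele liability effect at a locus with
frequency p is `w β / √(2p(1−p))` ≈ 0.05 liability SD, and the mean
liability of cases under a top-decile threshold is φ(z₀.₉)/K ≈ 1.75 SD, so
per-locus allelic odds ratios sit near `exp(0.05 × 1.9) ≈ 1.1` — an
infinitesimal-looking architecture. The TRS correlates with liability at
√η² ≈ 0.71 while the GRS correlates at √(ρ²η²) ≈ 0.35, which is the whole
point of the comparison: the TRS inherits the non-genetic variance flowing
through the mediating transcripts. The two scores themselves correlate at
√ρ² = 0.5.

## Estimation layer

* **eQTL scan** — per-locus OLS of expression on raw dosage (intercept
  included), computed from the closed-form normal equations across all loci
  at once. Monomorphic loci are flagged, warned about, and excluded from
  polarity and from both scores symmetrically.
* **Risk alleles** — the counted allele is called risk-increasing when its
  mean dosage in cases exceeds that in controls; exact ties resolve to the
  counted allele (and are reported). This is the simplest estimator
  consistent with the verbal rule that defines polarity.
* **Polarity** — `p̂_i = +1` when the risk allele increases expression,
  i.e. `p̂_i = ŝ_i` if the risk allele is the counted allele and `−ŝ_i`
  otherwise; a numerically zero slope resolves its sign to +1. Both an
  estimated and an `oracle` mode (reading the generative `s_i`, `d_i`) are
  provided so estimation error can be separated from scoring behaviour.
  Estimation is in-sample on the full cohort: no train/test split is
  applied by default, matching the simulation the package reproduces.
* **Standardization** — expression z-scores use the full-cohort sample mean
  and SD (denominator N − 1), cases and controls pooled. Controls-only
  standardization would shift the TRS by a constant per locus and leave
  every rank-based result (AUC, ROC) unchanged.

## Evaluation layer

* **AUC** is the Mann–Whitney estimator from midranks (ties count half),
  which equals the trapezoidal area under the ROC curve swept over unique
  observed thresholds; both identities are enforced by property tests
  against an exhaustive pair-enumeration oracle and against an independent
  ROC implementation.
* **ΔAUC significance** uses a paired percentile bootstrap (default 1,000
  resamples of individuals, both scores resampled with the same indices);
  degenerate single-class resamples are redrawn. An analytic variance
  formula would be faster but harder to verify; at N = 100,000 the
  percentile interval is already very tight.
* **Allelic odds ratios** come from per-locus 2×2 risk-allele × disease
  allele-count tables (two allele observations per individual). If any cell
  is zero, 0.5 is added to all four cells of that table (Haldane–Anscombe).
  "Effect size per locus" could also have been a genotypic OR or a logistic
  coefficient; the allelic OR is the recorded choice and the only one
  implemented. Medians over an even count are the mean of the two central
  order statistics (R's default).
* **Top-decile overlap** counts individuals in the top `floor(N/10)` of
  both scores, with ties broken by individual index for determinism.

## Randomness and reproducibility

One seed drives a single generator per cohort; sub-streams are drawn in a
fixed documented order (allele frequencies, direction signs, genotypes,
expression noise, liability noise), so `simulate_cohort()` is a pure
function of its config. Replicate r of an experiment uses
`base_seed + r`. Identical specs yield byte-identical exported artifacts.

## What the simulation does and does not emulate

The generator reproduces the *study conditions* of the reference
experiment: independent common variants, one eQTL per gene, additive
effects everywhere, equal per-gene weights, and expression measured without
error in exactly the tissue where it mediates risk. Real data violate most
of these: linkage disequilibrium correlates loci, eQTLs are shared and
context-dependent across tissues, transcript effects on liability are
unequal and partly non-additive, and expression is noisy. Passing tests
therefore show that the scoring and evaluation machinery behaves correctly
under the stated model — they do not show that a TRS will beat a GRS on any
particular real cohort, a question the package's external TSV interface
(`read_matrices()` + `as_cohort()`) lets users take to their own data.

## Problem sizes and numerical choices

The reference experiment (N = 100,000, M = 100, ρ² = 0.25, η² = 0.5,
K = 0.1) simulates in a few seconds per replicate; the acceptance suite
uses 25 replicates, and unit tests use cohorts of at most 20,000
individuals — sizes chosen so that sampling error sits well inside the
asserted tolerances (e.g. the mean per-locus r² over 100 loci at
N = 100,000 has a standard error of about 0.0007 against an asserted band
of ±0.005). Degenerate inputs are rejected rather than repaired:
monomorphic loci, zero-variance expression columns, single-class outcomes,
and configs whose implied case count is zero all raise typed errors.

## Known limitations

* No LD, trans-eQTLs, covariates, population structure, or missingness.
* Threshold-only disease; no probabilistic (probit/logistic) link.
* The GRS is unweighted and the TRS is the plain polarized sum; weighted,
  extreme-value, or pathway-structured score variants are out of scope.
* The MAF distribution, equal weighting, and fair-coin sign assignment are
  modelling choices of this package; the odds-ratio spread in particular is
  controlled by the MAF bounds.
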