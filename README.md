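# trscore

Transcriptional versus genotypic risk scores under a liability-threshold
disease model.

## The problem

Genotypic risk scores (GRS) summarise an individual's inherited disease risk
as an unweighted count of risk alleles across associated loci. Many of those
loci are expression quantitative trait loci (eQTLs): their alleles shift the
abundance of a nearby transcript, and it is plausibly the transcript — not
the genotype — that sits on the causal path to disease. When that is true, a
score built from the *expression* of those genes should predict disease
better than the allele count, because expression also captures the
non-genetic variation flowing through the same mediator.

`trscore` implements that comparison for researchers in statistical and
population genetics. The **transcriptional risk score (TRS)** of individual
*j* is the polarized z-score sum

```
TRS_j = Σ_i  p_i · z_ij ,      p_i ∈ {+1, −1}
```

where `z_ij` is gene *i*'s expression standardized over the cohort and the
polarity `p_i` is +1 exactly when the high-risk allele at gene *i*'s eQTL is
associated with *increased* expression — so higher TRS always means higher
inferred risk. The GRS is the plain oriented allele count `Σ_i c_ij` with
`c_ij ∈ {0, 1, 2}` risk alleles.

The package provides:

* a seeded generative model — genotypes under Hardy–Weinberg proportions,
  transcripts `T_i = s_i β x_i + e_i` with each cis-eQTL explaining a fixed
  fraction ρ² of transcript variance, liability
  `L = Σ_i d_i w_i T_i + ε` with the transcripts jointly carrying a fraction
  η² of liability variance, and disease assigned to the top K-quantile of
  liability;
* per-locus eQTL scans (OLS slope, r², sign), risk-allele calls and
  polarity estimation, with an oracle mode that reads the generative truth;
* GRS/TRS computation, Mann–Whitney AUC and ROC curves, paired-bootstrap
  confidence intervals for the AUC difference, per-locus allelic odds
  ratios with Haldane–Anscombe correction;
* a replicate-level experiment runner, tidy TSV import/export for external
  genotype/expression/phenotype matrices, ggplot2 figures, and a thin
  command-line wrapper (`inst/cli/trscore.R`).

## Worked example

```r
library(trscore)

cfg <- architecture_config(seed = 101)   # defaults: N = 100,000, M = 100,
                                         # rho^2 = 0.25, eta^2 = 0.5, K = 0.1
cohort <- simulate_cohort(cfg)
scan   <- eqtl_scan(cohort, polarity_source = "oracle")
scores <- compute_risk_scores(cohort, scan)
evaluate(cohort, scores, n_boot = 200)
```

```
<trs_evaluation>
  AUC: TRS 0.8724 vs GRS 0.6909 (delta 0.1815, 95% CI [0.1773, 0.1862])
  allelic OR: median 1.1147, second largest 1.1966
  GRS-TRS Pearson r = 0.4981; top-decile overlap 3166; 10000 cases / 90000 controls
```

The TRS separates cases from controls far better than the GRS (AUC 0.87 vs
0.69; the bootstrap interval for the difference is far from 0), even though
the two scores are only moderately correlated (r ≈ 0.50, the theoretical
√ρ²) and only about a third of the top-decile individuals coincide — the
individuals flagged as highest-risk genuinely differ between the two scores.
Meanwhile every per-locus allelic odds ratio is tiny (median ≈ 1.11, all
near or below 1.2): an architecture that is invisible locus-by-locus in a
case-control table can still be strongly predictive through expression.

`autoplot(evaluate(...))` draws both ROC curves; `plot_score_scatter()` and
`plot_or_distribution()` show the GRS–TRS joint distribution and the
odds-ratio histogram.

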