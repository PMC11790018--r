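---
title: "Methods: dependency screening, dose response and methylation biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dependency screening, dose response and methylation biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`methylscreen` implements an integrative pipeline for nominating DNA
methylation biomarkers of drug sensitivity and genetic dependency in
panels of cancer cell lines. The analytical chain is:

1. **Pooled CRISPR screen dependency scoring** — guide-level counts from
   an endpoint screen are compared with a day-0 plasmid reference to
   produce gene-level dependency scores (β-scores), anchored so that
   nontargeting controls sit at 0 and core-essential controls at −1.
2. **Cohort-level dependency statistics** — two-group (pediatric vs
   adult) differential dependency with Benjamini–Hochberg FDR control,
   hit calling, prevalence contingency analysis, and per-line gene
   ranking.
3. **Dose–response quantification** — four-parameter logistic (4PL)
   fits per cell line and drug, AUC over log-dose, and
   sensitive/resistant classification at an IC50 threshold.
4. **Random-forest biomarker nomination** — multi-omics feature
   assembly, correlation prefiltering, cross-validated regression
   forests on drug AUC, ranked-importance normalization, and
   single-correlate (waterfall) analysis.
5. **CpG cluster analysis** — correlation-based hierarchical clustering
   of locus CpGs, β-value binarization, and Fisher-exact scanning of
   binarization cutoffs.

Every stage is exercised end-to-end on a synthetic cohort with planted
ground truth, so the whole pipeline is testable without access to any
proprietary cell-line panel.

# The synthetic cohort and what it emulates

`truth_config()` fixes the study conditions; `generate_cohort()` draws a
cohort from them. The defaults describe a panel of 65 pediatric and 10
adult high-grade glioma-like cell lines in which a co-methylated CpG
cluster at one locus (`BCL2L1` in the generated annotation) drives both
a gene dependency (`MCL1` in the generated library) and sensitivity to
an inhibitor of that gene.

**Methylation.** Each sample carries a binary methylation state, drawn
with probability 0.75 (pediatric) or 0.10 (adult). The 44-CpG locus
contains a 10-site cluster whose values share a per-sample latent draw:
Beta(5, 2) truncated to [0.5, 1] for methylated samples (mode 0.8) and
Beta(1.3, 3.7) truncated to [0, 0.5) for unmethylated samples (mode
0.1). Site-level Gaussian jitter (sd 0.05) is *reflected* at the state
boundary, so every cluster site stays on its sample's side of β = 0.5.
This truncation is what plants the separation exactly at 0.5: with an
untruncated two-mode mixture at these modes, the minimum-misclassification
boundary of a 49:26 methylated:unmethylated cohort falls near β ≈ 0.42,
and a cutoff scan would legitimately prefer 0.4. The two-parameter
bounded distributions mirror the bimodal behavior of methylation-array
β-values. A second block of 8 sites is uniformly lowly methylated
(shared latent from Beta(1.5, 20), mean ≈ 0.07, below the 0.1 exclusion
threshold); remaining locus sites and background CpGs are independent
with intermediate site-specific means, so they fall apart into
singletons under correlation clustering.

**Expression.** The locus target gene has expression
`10 − slope · meanClusterβ + ε`. When `expr_noise_sd = NULL` the noise
variance is solved from the realized sample moments so that the Pearson
correlation between the target gene and the exemplar cluster CpG matches
`target_expr_corr` (−0.87 by default). All other genes are independent
noise.

**Screen counts.** The guide library has 352 genes × 4 guides (62 of
them core-essential positive controls) plus 250 nontargeting guides
grouped under two pseudo-genes — 1,658 guides. Day-0 plasmid counts are
negative-binomial around 500 reads/guide with dispersion 0.02
(variance = μ + 0.02 μ²); endpoint expectation is the day-0 expectation
times `2^(gene effect + guide jitter)`, guide jitter N(0, 0.1). The
marker gene's true effect is −0.92 in methylated and −0.18 in
unmethylated samples; essential controls are −1, nontargeting 0, and 20
further target genes get fixed effects drawn once from
Uniform(−0.8, 0.2) so that estimator recovery is measured across a
spread of true effects while the marker remains the strongest planted
target dependency. The dispersion default keeps replicate log-count
correlations near 0.7, i.e. a screen that passes its own QC gate
(r > 0.5) comfortably, as a well-executed screen should.

**Dose response.** Twelve doses: 0 plus 11 half-log-spaced points up to
20 µM (the spacing is a package choice; only the 12-point 0–20 µM frame
is fixed). True IC50s are lognormal (log10 nM mean 2.6, sd 0.4) for
methylated samples and ≥ 40 µM (beyond the tested range) for
unmethylated ones. Viability is 4PL (top 1, bottom 0, hill 1) plus
Gaussian noise (sd 0.05) clipped to [0, 1.2] — assays occasionally
report super-100% viability, and viability cannot be negative. Wells
are duplicated per dose.

**What it does not emulate.** No array probe chemistry or IDAT-level
artifacts, no tumor-purity mixtures (patient specimens dilute
methylation signal with nontumor cells; no purity adjustment is made
anywhere in the package), no guide-efficiency or copy-number artifacts
in the screen, and no correlation structure among background features.
Passing recovery tests therefore demonstrates the estimators are
correct and well-calibrated under the assumed generative structure, not
that they are robust to every artifact of real data.

# Dependency scoring

Counts are scaled to counts-per-million, offset by a pseudocount of 1
and log2-transformed. The per-guide log2 fold-change (endpoint −
reference, averaged over replicates) is aggregated to the gene level by
the **median across the gene's guides** — a deliberate simplification
relative to regression-based β-score estimators; it is robust, fully
specified, and demonstrably recovers planted effects. Scores are then
anchored per cell line by the affine map
`(raw − m_NT) / (m_NT − m_ESS)`, which sends the nontargeting-gene
median to 0 and the essential-control median to −1 exactly. If the two
control medians coincide the screen is uninformative and scoring stops
with an error.

Differential dependency uses Student's equal-variance t-test by default
(Welch's behind a flag), BH adjustment across tested genes, and the
call gates Δ ≥ 0.1 with FDR < 0.05, where Δ = mean(adult) −
mean(pediatric). Genes with zero variance in both groups are flagged
and reported at p = 1 rather than raising. Hits are β ≤ −0.5, boundary
inclusive; the threshold is negative because dependency scores are
depletion scores (reduced viability on knockout). Display percentages
round half-up to integers.

# Dose–response fitting

`fit_four_pl()` minimizes least squares over
`v(d) = bottom + (top − bottom) / (1 + (d/IC50)^hill)` using bounded
Levenberg–Marquardt from 24 grid-initialized starts (8 log-spaced IC50
starts × hill starts 0.5/1/2). Doses are handled internally in nM.
Zero-dose wells are excluded from the fit and serve only as the
100%-viability control. Bounds: top ∈ [0.5, 1.5], bottom ∈ [0, 0.7],
hill ∈ [0.2, 5]. The lower asymptote is bounded at 0 because viability
is a fraction of control; allowing it negative makes the IC50
non-identifiable for curves that do not bottom out within the tested
range. A fit is right-censored — IC50 reported at the maximum dose —
when the fitted IC50 exceeds the maximum dose, the fitted dynamic range
(top − bottom) is under 0.2, or the observed mean viability at the top
dose stays above 0.5 (the data never demonstrate half-kill).

At viability noise sd 0.05 on a triplicate 12-point grid, per-curve
IC50 uncertainty is intrinsic, not algorithmic: even a brute-force fit
with all other parameters fixed at their true values shows a typical
relative error of several percent, and the free 4PL runs at roughly 1.2
times that information floor. The test suite therefore asserts batch
mean/median recovery error and per-curve dominance over a brute-force
grid-search oracle on the shared objective, rather than a per-curve
error bound.

AUC is the trapezoidal integral of raw mean viability over log10(dose)
across the nonzero doses, divided by the log-dose span, so a flat
nonresponder scores exactly 1; it deliberately uses measurements rather
than the fitted curve so it remains defined when fits fail. Normalized
AUC divides by a reference line's raw AUC. Sensitivity is IC50 < 2 µM,
strict, with censored fits resistant. The alternative stated threshold
(log10 IC50 of 3.5 in nM ≈ 3.16 µM) is reported alongside but 2 µM is
canonical.

# Random-forest biomarker nomination

Features are assembled per modality: expression and methylation blocks
are reduced to the top-k most variable features (default 8,000; ties by
feature id) and standardized; mutation/CNV binaries pass through;
clinical categoricals are one-hot encoded. Samples missing from any
block are dropped with a warning. A correlation prefilter keeps the
`prefilter_k` (default 400) features with largest |Pearson r| against
the response (drug AUC); the prefilter is computed once on the full
cohort, before cross-validation — a pragmatic choice that mildly biases
out-of-fold performance upward and is recorded in the provenance log,
so out-of-fold skill should be read as a relative diagnostic, not an
unbiased generalization estimate.

The forest (`ranger`, single-threaded for determinism) is a regression
on continuous AUC by default — the single-correlate analysis is against
AUC, so regression is primary — with a sensitive/resistant
classification mode available. Performance is summarized by out-of-fold
Spearman correlation and R²; raw importance is seeded permutation
importance averaged over the fold models (impurity importance behind a
flag; permutation is less biased across mixed modality scales).

`normalize_importance()` sorts importances descending and reports each
feature's **normalized score = importance / max importance**, flagging
features at or above 0.3 as top contributors. The ranked-importance
profile's least-squares gradient is also computed, and
|gradient| / (max importance × feature count) is reported as a
model-level concentration diagnostic. The per-feature reading keeps the
0.3 threshold well-defined on [0, 1]; the gradient quantity is retained
because a model whose importance mass is concentrated in a few features
has a steeper profile, which is useful when comparing models. Negative
permutation importances are clipped at zero before normalization.

# CpG clustering and cutoff scanning

Locus CpGs are clustered on the distance 1 − r (pairwise Pearson
correlation of sites across samples) with average-linkage agglomeration
and a fixed tree cut at height 0.5 — i.e. sites stay together while
their mean inter-correlation stays above ≈ 0.5. A fixed cut height,
rather than a fixed cluster count, discovers "tightly correlated"
blocks without assuming how many there are; both linkage and height are
configurable. Clusters with mean β < 0.1 are flagged uniformly lowly
methylated and excluded from biomarker candidacy; 0.1 operationalizes a
qualitative notion. Constant rows get zeroed correlations with a
message.

Binarization calls a sample methylated at β ≥ cutoff (boundary
inclusive, default 0.5). `scan_threshold()` evaluates a candidate grid
(default 0.1–0.9 by 0.1) by two-sided Fisher's exact test of the
binarized state against sensitive/resistant labels, recording
degenerate cutoffs (an empty margin) at p = 1 and choosing the
minimal-p cutoff, smallest on ties. The per-cutoff p-values are
reported uncorrected and the scan is marked exploratory: selection over
cutoffs is not adjusted for, so under a null response about 1 in 20
scans will still show a nominally significant best cutoff.

`fisher_exact_2x2()` uses the probability-mass convention for the
two-sided p (sum of hypergeometric probabilities of tables at most as
probable as observed, fixed margins) — the dominant convention in
scientific software — and reports the sample cross-product odds ratio
(a·d)/(b·c), flagged undefined on 0/0. The implementation is checked in
the test suite against exhaustive enumeration of all tables with the
observed margins.

Age-group summaries reduce each sample to either the mean β over a site
set or the global median β over all CpGs, split pediatric/adult at age
21 (pediatric strictly below), and compare groups by an unpaired
t-test.

# Numerical choices and degenerate inputs

* All randomness flows from a single integer seed; generators derive
  fixed offsets from it, and the forest seeds fold assignment and each
  fold's trees. Identical configuration + seed reproduces every table
  byte-identically.
* Ties are broken deterministically everywhere: lexicographic feature
  or gene ids in rankings and selections, smallest cutoff in scans,
  first-minimum in grid searches.
* Zero-variance features correlate at r = 0 (flagged), never NA.
* Percent displays round half-up; internal values are never rounded.
* Sample sizes in the test suite are scaled to the analysis: full
  75-line cohorts where recovery at the study's size is the claim
  (estimator recovery, FDR control, biomarker nomination; 5–20 seeds),
  and 20-line cohorts for structural checks.

# Known limitations

* The gene aggregation is a median-of-guides estimator, not a
  maximum-likelihood β-score; absolute scores agree with planted truth
  under the generator but may differ from likelihood-based estimators
  on real screens with variable guide efficiency.
* No copy-number correction of screen data, no guide-efficiency
  modeling, no combination/synergy dose-response models.
* The cutoff scan reports uncorrected p-values (see above).
* Tumor-purity effects on methylation are documented but not modeled;
  thresholds tuned on cell lines (β ≥ 0.5) are expected to shift
  downward in impure patient specimens.
* In vivo screen essentiality conventions that report positive scores
  are out of scope; the package reports signed β and ranks only.
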