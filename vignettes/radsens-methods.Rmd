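---
title: "Methods: rank-based radiosensitivity scoring and its immune associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based radiosensitivity scoring and its immune associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsens)
```

## The model

The radiosensitivity index (RSI) is a rank-based linear score over ten
genes (AR, JUN, STAT1, PRKCB, RELA, ABL1, SUMO1, CDK1, HDAC1, IRF1). For
each sample the ten genes are ranked among themselves by expression —
the highest-expressed gene receives rank 10, the lowest rank 1, ties get
average ranks — and the score is the weighted sum

$$\mathrm{RSI}_j = \sum_{g=1}^{10} c_g \, r_{gj},$$

with the fixed published coefficients `c_g` returned by `rsi_signature()`.
The score proxies the clonogenic surviving fraction at 2 Gy, so a *low*
RSI means *high* radiosensitivity. Because only within-sample ranks enter,
the score is invariant under any strictly monotone per-sample transform of
expression — the property that lets one signature travel between
microarray and RNA-seq platforms, and the property our QC report
(`qc_signature()`) checks directly.

Three consequences of the rank formulation shape the implementation:

* ranks are computed **among the ten signature genes only** (this is the
  only reading under which the top gene can be "ranked 10");
* the ranks of a sample always sum to 55 under average-rank ties, so a
  fully tied sample scores $5.5 \sum_g c_g \approx 0.30700$;
* the score is an unbounded linear form: over all rank permutations it
  spans $[-0.60510,\ 1.21910]$, the rearrangement-inequality extremes.
  No clipping is applied.

Samples are stratified at a cut-off $\theta$: RSI-Low if
$\mathrm{RSI} < \theta$, RSI-High otherwise. The default $\theta = 0.46$
is the published cut-point; 0.3745 has been used in clinical work and can
be passed instead. The strict-less convention for RSI-Low is our choice —
the boundary sample is not defined in the source literature — and keeps
the High stratum closed at the published value.

## Single-sample enrichment

T-cell-inflamed activity (TCIA) is scored per sample with a GSVA-style
statistic, implemented in full here:

1. **Kernel CDF**: each expression value is replaced by its Gaussian-kernel
   cumulative density against the gene's own cross-sample distribution
   (bandwidth = per-gene sd / 4, the conventional default). A constant
   gene is assigned 0.5 everywhere and logged.
2. **Centred ranks**: per sample, genes are ordered by decreasing
   statistic; gene at rank $r$ receives weight $|p/2 - r|$.
3. **Weighted KS walk**: stepping down the ordering, the walk rises by the
   normalised weight$^\tau$ ($\tau = 1$ by default) at set genes and falls
   uniformly at non-set genes; the score is the maximum positive plus the
   minimum negative deviation ("max-diff" scoring).

Scores are z-transformed cohort-wise using the population standard
deviation (so the cohort z has mean exactly 0 and sd exactly 1), and a
sample is called enriched when $z > \theta_z$. The default
$\theta_z = 0.35$ follows the melanoma-derived threshold; 0.32 also
appears in the same literature, and both are plain arguments. We note the
two values without resolving them: with a single gene set, the per-sample
z-score is the quantity thresholded.

The shipped 18-gene T-cell-inflamed list (`tcia_gene_set()`) is the
published PD-1-blockade response signature; it shares exactly one gene
(STAT1) with the RSI list. It ships as an editable data file because the
list is a reference input, not part of the algorithm.

## Immune association statistics

* **Macrophage polarisation**: $\log_2(\mathrm{M1}/\mathrm{M2})$ per
  sample from deconvolved immune fractions (deconvolution itself is an
  input, not reimplemented). Zero fractions are structural — the cell type
  was called absent — so affected samples are excluded and counted rather
  than pseudo-counted; a pseudo-count would silently shape the reported
  correlation with RSI.
* **Correlation matrices**: Spearman rho with pairwise-complete
  observations; exact p for $n \le 10$ without ties, asymptotic t
  otherwise; cells with fewer than 4 pairs are flagged missing. P-values
  are reported raw: the source workflow states no multiplicity adjustment,
  and none is applied — this is documented rather than silently "fixed".
* **Group comparisons**: two-sided Mann-Whitney U (exact enumeration over
  all group assignments when both groups have $\le 8$ observations,
  tie-corrected normal approximation with continuity correction
  otherwise) and classical one-way ANOVA across $k$ groups.
* **Differential filter**: from a supplied differential table (e.g. an
  edgeR-style proteomic result), features with $|\log FC| > 1$ and
  adjusted $p < 0.05$ are retained, both inequalities strict. The
  negative-binomial fit itself is out of scope; only the filter rule is
  reproduced.

## The C2 classifier

The IFN-γ-dominant (C2) immune subtype is classified from the ten RSI
genes with a random forest (500 trees, `mtry` = floor(sqrt(p)), the
canonical defaults of the reference implementation; a seed is mandatory).
Feature importance is the mean decrease in Gini impurity (MDG); genes with
MDG strictly above the mean importance are selected. Evaluation uses
stratified 5-fold cross-validation with pooled out-of-fold predictions —
the source procedure does not state its split, and cross-validation avoids
an optimistic resubstitution estimate without inventing a holdout. The
report carries accuracy with an exact Clopper–Pearson binomial CI, the
rank-formulation (Mann–Whitney) AUC, and ROC points.

Optimal score cutpoints use the Youden index over midpoints between
consecutive distinct scores; the direction (positives above or below the
cut) is chosen from the data, so relabelling classes returns the same
cutpoint with sensitivity and specificity swapped, and ties break toward
the lower cutpoint.

## Survival

Kaplan–Meier estimation, the two-group log-rank test and the univariate
Cox fit (Efron ties, Newton iteration, Wald CI) are delegated to the
standard survival toolchain behind this package's interface. The optimal
survival cutpoint — the value maximising the standardised log-rank
statistic over admissible splits leaving at least `minprop` (default 0.1)
of samples per side — is implemented here as a scan over midpoints.
Selecting and testing the cutpoint on the same cohort replicates the
source workflow but biases the resulting p-value downward; the
documentation and the analysis driver both surface this caveat, and the
null-configuration test validates on an independent replicate.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so the full chain is testable without external data:

* **Expression**: per-gene baseline mean + Gaussian noise on a log-like
  scale. The signature genes (RSI ∪ TCIA) share a common baseline mean
  so that within-sample ranks are driven by per-sample noise and the
  subtype effect; a wide spread of baseline means would freeze the rank
  ordering across samples, collapsing score variance and making
  stratification degenerate. Background genes get dispersed means.
* **C2 effect**: C2 samples receive a `delta_rsi`-sd shift on the five
  classifier genes via the signed pattern `default_c2_pattern()` (+ on
  JUN, STAT1, CDK1, IRF1; − on ABL1) and a `+delta_tcia`-sd shift on the
  TCIA genes. Because the score mixes positive and negative coefficients,
  the sign pattern was calibrated once against the rank scorer
  (`analysis/00_calibrate_direction.R` re-derives it): the four genes
  observed higher in radiosensitive tumours point up, and ABL1 — the
  dominant positive weight — points down, which guarantees C2 samples
  score lower, the direction the analysis assumes.
* **Immune fractions**: Dirichlet draws over 22 cell types
  (concentration 2 per component, a mildly even profile in which zero
  fractions are rare), then the M1 component gains
  `beta_m1 · max(0, θ − RSI)` mass and the vector is renormalised —
  couplings stay on the simplex by construction.
* **Survival**: exponential event times with hazard
  `baseline_rate · hazard_ratio^(RSI ≥ θ)` and independent exponential
  censoring.

Defaults (n = 600 samples, 500 background genes, subtype mix 35/25/15/10/5/10%
over C1–C6 with C1/C2 dominant as observed in pan-cancer immune-subtype
catalogues, 1.5-sd effects, noise sd 1, `beta_m1` = 0.5, baseline rate 0.1,
hazard ratio 2, censoring rate 0.05) are chosen for realistic effect
recovery at this cohort size; no effect-size estimates exist in the source
for the C2 shifts, so these are testability choices, documented as such.
Everything is reproducible: the same config and seed regenerate the cohort
bitwise-identically.

What the generator does **not** emulate: batch effects and cross-platform
merging artefacts, realistic pan-cancer gene–gene covariance, cancer-type
structure within subtypes, and deconvolution noise in the immune
fractions. Passing tests therefore demonstrate that the *procedures* are
implemented correctly and recover planted structure — not that the
published external-cohort effect sizes (classifier accuracy 82%, AUC
0.8449, specific Spearman rhos, cohort HRs) are reproduced; those require
the original data and are explicitly out of scope.

## Numerical choices and degenerate inputs

* Ties: average ranks everywhere (preserves the rank-sum invariant).
* A missing signature-gene value fails scoring loudly, naming the gene and
  sample; nothing is imputed.
* Kernel statistic requires ≥ 3 samples; z-scoring requires ≥ 2 samples
  and non-zero variance; constant genes get statistic 0.5 with a log
  message.
* Cutpoint scans use midpoints between consecutive distinct observed
  values, removing dependence on score granularity; ties break toward the
  lower candidate.
* Cox fits failing to converge in 50 iterations, or with a monotone
  likelihood, are flagged rather than silently reported.
* Probe collapse takes per-sample maxima, excluding missing cells; a
  probe absent from the map is an error by default (droppable on request).

## Problem sizes used in the shipped analyses

The analysis drivers and tests run at n = 600 samples with ~530 genes,
500-tree forests, and 5-fold cross-validation; oracle checks enumerate all
10! rank permutations directly. These sizes give stable recovery of every
planted effect while keeping each analysis script in the seconds range.

## Known limitations

* The enrichment statistic implements the default kernel-CDF pathway
  only (no empirical-CDF count mode, no multi-set matrices).
* Correlation p-values are unadjusted (documented above).
* The survival cutpoint inherits the selection-on-test-data bias of the
  workflow it reproduces.
* The generic scoring engine can host other weighted rank signatures if
  coefficients are supplied, but only the ten-gene RSI instance ships;
  other published radiosensitivity signatures print no coefficients in
  our sources.
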