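# radsens

Rank-based radiosensitivity scoring and its immune associations, as a
tested R package plus a reproducible analysis workflow.

Tumours that respond to radiotherapy tend to carry a distinctive immune
configuration, and a genomic score of radiosensitivity can double as a
candidate selection marker for combined radio- and immunotherapy. This
package implements that analytic chain end to end for researchers working
with bulk expression cohorts:

* **RSI scoring** — the ten-gene radiosensitivity index: per sample, the
  genes AR, JUN, STAT1, PRKCB, RELA, ABL1, SUMO1, CDK1, HDAC1 and IRF1 are
  ranked among themselves (highest expression = rank 10) and combined
  linearly,

  RSI = −0.0098009·AR + 0.0128283·JUN + 0.0254552·STAT1 − 0.0017589·PRKCB
  − 0.0038171·RELA + 0.1070213·ABL1 − 0.0002509·SUMO1 − 0.0092431·CDK1
  − 0.0204469·HDAC1 − 0.0441683·IRF1,

  where each gene symbol stands for its within-sample rank. Low RSI =
  high radiosensitivity. Cohorts are stratified at the published cut-off
  0.46 (overridable), with cross-platform signature QC.
* **Single-sample enrichment** — a fully implemented GSVA-style statistic
  (Gaussian-kernel CDF → centred ranks → weighted KS walk) scoring the
  18-gene T-cell-inflamed signature per sample, z-transformed cohort-wise
  and thresholded at 0.35.
* **Immune associations** — log2(M1/M2) macrophage polarisation, Spearman
  correlation matrices with p-values, Mann-Whitney and one-way ANOVA group
  comparisons, and the strict |logFC| > 1 & adjusted p < 0.05 filter for
  differential tables.
* **C2 classification** — random-forest mean-decrease-in-Gini importance
  of the RSI genes for the IFN-γ-dominant immune subtype, above-mean
  feature selection, cross-validated forest classifier with
  Clopper-Pearson CI and rank-formulation AUC, and Youden-index cutpoints.
* **Survival** — Kaplan-Meier curves, log-rank tests, univariate Cox
  hazard ratios and maximally selected survival cutpoints.
* **Synthetic cohorts** — a seeded generator producing expression,
  subtype labels, immune fractions and survival with known planted
  structure, so every stage is testable without external data.

## Worked example

```r
library(radsens)

co  <- generate_cohort(synthetic_config(seed = 101))        # 600 samples
run <- run_pipeline(co, pipeline_config(seed = 101))
cat(pipeline_report(run), sep = "\n")
```

Output (abridged):

```
## RSI scores
n = 600; median 0.1581 (IQR -0.0721-0.5067); 432 RSI-Low / 168 RSI-High at threshold 0.46.

## T-cell-inflamed enrichment
27.0% of samples enriched at z > 0.35.
Enrichment by RSI stratum:
  E: 4 / 158
  NE: 164 / 274
Spearman rho(RSI, tcia_z) = -0.327 (p = 1.85e-16, n = 600).
Spearman rho(RSI, log2_m1_m2) = -0.691 (p = 2.69e-86, n = 600).

## C2 classifier
Selected genes: JUN, STAT1, ABL1, CDK1.
Accuracy 0.970 (95% CI 0.953-0.982); AUC 0.9900 (stratified 5-fold CV).

## Survival
Log-rank chi-square 28.13 (p = 1.14e-07).
Cox HR (RSI-High vs RSI-Low) 1.741 (95% CI 1.415-2.143).
```

Reading it: in this coupled synthetic cohort, T-cell-inflamed enrichment
concentrates almost entirely in the RSI-Low stratum (158 of 162 enriched
samples), RSI correlates negatively with both enrichment and M1-macrophage
polarisation, the classifier recovers the informative genes, and the
planted survival difference between strata is detected — the qualitative
pattern the score is designed to expose in real cohorts.

## The analysis workflow

`analysis/` contains numbered drivers that run the same chain as explicit
scripts writing tables under `results/`:

```sh
Rscript analysis/00_calibrate_direction.R   # derives the C2 shift pattern
Rscript analysis/01_simulate.R              # generates the study cohort
Rscript analysis/02_score_qc.R              # RSI scores + signature QC
Rscript analysis/03_enrichment_immune.R     # enrichment + associations
Rscript analysis/04_classifier.R            # C2 classifier
Rscript analysis/05_survival.R              # survival stratification
```

`vignettes/radsens-methods.Rmd` documents the models, defaults and the
design decisions behind them.

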