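# resistseq

Cross-cohort discovery of a chemoresistance gene panel from bulk RNA-seq
TPM matrices, and prediction of platinum-chemotherapy resistance in
high-grade serous ovarian carcinoma (HGSOC) with a fold-wise deep
ensemble.

Small, imbalanced, batch-shifted cohorts are the working reality of HGSOC
transcriptomics. This package implements a workflow designed for exactly
that setting, for bioinformaticians who have several cohorts' TPM matrices
with resistant/sensitive labels (resistant = relapse within 6 months of
first-line platinum therapy):

1. **Preprocess** — merge cohorts on shared Ensembl IDs, drop lowly
   expressed genes (TPM ≥ 1 in ≥ 20% of pooled samples), split each
   cohort 2:1 with class stratification.
2. **Tier-1 genes** — per-cohort Student's t-tests on log2(TPM+1)
   (p < .05), intersected across all cohorts: the reproducible core.
3. **Tier-2 genes** — per cohort, 100 balanced bagging trials (bootstrap
   of min(n_res, n_sens) per class), keeping genes significant by
   Mann-Whitney U (p < .05) in more than 80 trials: cohort-specific but
   resampling-stable signal. The panel is the union of both tiers.
4. **Deep ensemble** — the primary cohort's training samples are split
   into 5 stratified folds; each fold is grid-searched over fully
   connected networks (Adam, binary cross-entropy; default grid 2160
   hyperparameter combinations) and the entry with the best ROC AUC on a
   *second* cohort's training data is kept. Predictions average the five
   winners: score = mean_k sigmoid_k(x).
5. **Evaluate** — ROC AUC plus a sensitivity-prioritized threshold
   (maximize specificity subject to sensitivity ≥ 1.0 for detecting
   resistance), and a random-panel null: retrain the whole ensemble on
   panels of the same size drawn uniformly from the filtered gene pool,
   empirical p = (1 + #{null ≥ observed}) / (1 + n_draws).

Because the cohorts this design targets are controlled-access, the package
ships a synthetic study generator: three cohorts at the published class
counts (149/59, 24/16, 14/72), cohort batch shifts on the log scale, and
planted shared plus cohort-specific differential genes with known
identities, so every stage is tested against ground truth.

## Worked example

The `analysis/` scripts run the whole study on the synthetic design
(`Rscript analysis/01_simulate.R` through `analysis/05_evaluate.R`,
tables land in `results/`). Stage 3 recovers the planted signal:

```
<gene_panel> 33 genes (tier1: 5; tier2: TCGA 11, Patch 18, SNUH 13)
               set planted recovered selected
      tier1_shared       5         5        5
TCGA    tier2_TCGA       5         5       11
Patch  tier2_Patch       5         5       18
SNUH    tier2_SNUH       5         5       13
```

All 5 planted shared genes are found by tier 1 with no false positives,
and each cohort's 5 planted specific genes are found by tier 2 (the extra
tier-2 selections are resampling-stable chance differences — see the
vignette on what the frequency filter does and does not control). Stages
4–5 train the ensemble (12-entry desk-scale grid) and evaluate:

```
  cohort       auc sensitivity specificity   threshold n_resistant n_sensitive
1   TCGA 0.9989259           1   0.5789474 0.004237865          49          19
2  Patch 0.9750000           1   0.0000000 0.004237865           8           5
3   SNUH 0.9791667           1   0.9583333 0.004237865           4          24

<null_comparison> 10 random panels of 33 genes
  null AUC: mean 0.461, 90th pct 0.666; observed 0.979; empirical p 0.0909
```

The threshold is tuned on the SNUH-like test split to the 100%-sensitivity
rule and applied everywhere, so sensitivity is 1 by construction there and
specificity is the quantity to watch. The discovered panel's AUC (0.979)
sits far above the random-panel null (mean 0.461), with the smallest
empirical p attainable from 10 draws (1/11 ≈ 0.091).

The same run is available as one call:

```r
library(resistseq)
man <- run_pipeline("pipeline.yaml", "runs/demo")  # see ?load_pipeline_config
```

which writes `panel.json`, `model/`, `report.json` and `manifest.json`
(config hash, per-stage seeds, output digests).

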