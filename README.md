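# cellrisk

Identification of disease-perturbed **risk cells** in multi-donor
single-cell cohorts, and staging of donors from their risk-cell
proportions.

In progressive diseases such as type 2 diabetes, a diseased donor's cells
of a given type are a mixture of normal and perturbed cells, with the
perturbed fraction growing along the ND → preT2D → T2D continuum.
`cellrisk` learns, per cell type, a **pseudo disease-state index**
$\pi_i \in [0,1]$ for every cell $i$ from donor-level ordinal labels: an
elastic-net binomial model on log-normalized expression, trained on
endpoint-state (ND vs T2D) cells under **donor-grouped cross-validation**
(no cell is ever scored by a model that saw its donor) and sharpened by
self-training refinement to cope with the label noise inherent in
donor-level supervision. Sorting the indexes and thresholding them — at a
fixed cutoff, a pooled quantile, or a sliding-window scan that maximizes
the Kruskal–Wallis separation of per-donor proportions across states —
yields binary risk calls. The per-donor risk proportion
$p_d = n_{\text{risk},d} / n_d$ is then the single staging feature:

* rule bands ($p < 0.10$ → ND, $0.10 \le p \le 0.20$ → preT2D,
  $p > 0.20$ → T2D),
* pairwise linear-SVM staging with leave-one-donor-out ROC/AUC and
  stratified bootstrap confidence intervals,
* Pearson association with clinical covariates (HbA1c, BMI, C-peptide),
* two-sided Wilcoxon rank-sum group comparisons with BH correction,
* risk-vs-nonrisk pseudobulk differential expression (paired
  negative-binomial Wald test), and
* Louvain subtype clustering with hypergeometric risk-aggregation
  dynamics across stages.

A negative-binomial cohort simulator with planted perturbation programs
and exact ground truth makes the entire workflow testable without any
external data.

## Worked example

```r
library(cellrisk)

sim <- simulate_cohort(sim_config(seed = 1))      # 30 donors x 200 cells x 1000 genes
idx <- compute_disease_index(sim$cohort, "beta", index_config(seed = 1))

truth <- sim$truth$cells$is_risk_true[match(idx$cell_id, sim$truth$cells$cell_id)]
roc_auc(idx$index, truth)$auc
#> [1] 0.9396312

sw   <- call_risk_sliding_window(idx, sim$cohort)
prof <- donor_risk_proportions(sw$risk, sim$cohort)
sw$threshold
#> [1] 0.65
tapply(prof$proportion, prof$state, mean)          # ND, preT2D, T2D
#>      0      1      2
#> 0.0640 0.1155 0.2305
mean(stage_by_rule(prof$proportion) == prof$state) # rule-band staging accuracy
#> [1] 0.8666667
```

The index separates truly perturbed cells from normal cells (AUROC 0.94
against the simulator's ground truth), the chosen threshold (0.65)
produces donor risk proportions that rise monotonically along the disease
continuum and sit near the planted 5%/15%/30% fractions, and the 10%/20%
rule bands stage 26 of 30 donors correctly. `fit_stage_classifier(prof)`
adds the pairwise SVM AUCs (1.00 / 0.96 / 1.00 on this cohort) and
`group_compare(prof)` the Wilcoxon contrasts.

The same workflow runs from a YAML config as one call —
`run_pipeline("cfg.yaml")` — or from the shell via the thin wrapper in
`inst/cli/cellrisk.R` (subcommands `simulate`, `index`, `call`, `run`).

## Package layout

| Area | Functions |
|---|---|
| data model | `new_cohort`, `load_cohort`, `write_cohort`, `subset_by_cell_type` |
| preprocessing | `qc_filter`, `normalize_log`, `select_hvg` |
| disease index | `index_config`, `assign_donor_folds`, `fit_index_model`, `predict_index`, `compute_disease_index` |
| risk calling | `call_risk_fixed`, `call_risk_quantile`, `call_risk_sliding_window`, `threshold_sensitivity` |
| staging/association | `donor_risk_proportions`, `stage_by_rule`, `fit_stage_classifier`, `roc_auc`, `bootstrap_auc_ci`, `pearson_assoc`, `group_compare`, `bh_adjust` |
| downstream | `pseudobulk_aggregate`, `de_test`, `subtype_cluster`, `risk_aggregation_dynamics` |
| simulation | `sim_config`, `simulate_cohort` |
| orchestration | `run_pipeline` |

See `vignettes/cellrisk-methods.Rmd` for the model, its assumptions, the
simulator's scope, and the package's numerical choices.
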