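---
title: "Risk-cell identification and proportion-based disease staging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-cell identification and proportion-based disease staging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellrisk)
```

## The problem

In progressive metabolic disease such as type 2 diabetes (T2D), a diseased
donor's cells of a given type are not uniformly abnormal: normal and
perturbed cells coexist, with the perturbed fraction growing along the
nondiabetic (ND) to pre-diabetic (preT2D) to T2D continuum. Donor-level
labels are therefore noisy cell-level labels, and differential analyses
keyed to donor labels dilute signal over the majority of unperturbed cells.

`cellrisk` addresses this by assigning every cell of one cell type a
*pseudo disease-state index* in $[0,1]$ — learned from donor-level ordinal
labels but expressing a cell-level ranking along the healthy-to-diseased
continuum — and calling cells above a threshold *risk cells*. The fraction
of a donor's cells called risk is then a single-feature marker used for
staging, clinical association, and molecular contrasts.

## The index model

For a chosen cell type, counts are library-size log-normalized
($\ln(1 + s\,c_{ij}/t_i)$ with scale $s = 10^4$ and per-cell totals $t_i$
computed over the full gene set), optionally restricted to the most
variable genes, and fed to an elastic-net-regularized binomial linear
model. Training cells come only from the endpoint states: cells of ND
donors are labeled 0, cells of T2D donors 1, with inverse-frequency class
weights. The fitted probability is the index.

Three design choices do the real work:

* **Donor-grouped cross-validation.** Donors of each endpoint state are
  split evenly across folds; each cell is scored only by the model whose
  training folds excluded its donor. Without this, donor-specific
  expression signatures — perfectly label-predictive within the training
  donors — would inflate cell-level performance without carrying any
  disease information. The fold provenance is recorded per cell, making
  the no-leakage property assertable after the fact.
* **Self-training refinement.** A single fit on donor labels plateaus well
  short of the attainable cell-level accuracy, because most cells of a
  diseased donor are not perturbed (at a 30% risk fraction, 70% of the
  positive training labels are wrong). After the initial fit, the positive
  set is restricted to T2D-donor cells scoring above the 0.95 quantile of
  the ND-donor cells' scores, and the model is refit; six iterations
  concentrate the positive class on genuinely perturbed cells (observed
  purity rises from ~0.30 to ~0.75 on simulated cohorts). The final refit
  relaxes the penalty to 0.4x since the refined labels are cleaner.
  Refinement happens strictly inside each training fold, so the
  cross-validation guarantee is untouched.
* **preT2D cells are never trained on.** They are scored as the mean of
  all fold models (`fold = -1`), so their intermediate placement on the
  continuum is a genuine prediction, not an artifact of having anchored
  them during training.

Strong regularization (default $\lambda = 0.05$, $\alpha = 0.5$) is
deliberate: with tens rather than hundreds of training donors, weak
penalties let the model latch onto donor signatures; the donor-consistent
disease program survives the penalty, donor idiosyncrasies do not. The raw
model probability is used as the index with no per-cell-type rank
re-normalization, so fixed thresholds are read on the probability scale.

## Risk calling

Three interchangeable rules convert indexes to binary calls, all with a
strict greater-than comparison at the threshold:

* `call_risk_fixed()` — a fixed cutoff (default 0.89, the fixed
  probability-scale cutoff used for beta cells in real-cohort analyses).
* `call_risk_quantile()` — the pooled type-7 (linear interpolation)
  empirical quantile of the indexes.
* `call_risk_sliding_window()` — scans a threshold grid and picks the
  value maximizing the Kruskal–Wallis statistic of per-donor risk
  proportions across disease-state groups, subject to an overall risk
  fraction of at least `min_risk_fraction` (default 0.01, ruling out the
  degenerate flag-nothing optimum). Ties break toward the largest
  threshold. This criterion is this package's construction of the
  sliding-window idea: it is rank-based and uses all three states.

The simulation workflow defaults to the sliding window. One caveat is
documented deliberately: because the window *optimizes* donor separation,
re-measuring separation (e.g. a staging AUC) at the chosen threshold on
the same donors is upward-biased when no signal exists. Null calibration
checks in this package therefore measure staging at a non-adaptive
quantile threshold ($q = 0.9$); `threshold_sensitivity()` exposes the full
threshold-response surface for the signal case.

A second caveat: the Kruskal–Wallis criterion is rank-based, so it selects
for *separation* of donors, not for calibration of the absolute proportion
level. When several thresholds order donors identically, the criterion is
flat between them, and the chosen cutoff can land where proportions are
systematically higher or lower than the underlying perturbed fractions.
Rule-band staging, which reads proportions on an absolute scale, is
therefore more stable when paired with a fixed or quantile threshold, and
`threshold_sensitivity()` should be consulted before trusting band
assignments at a window-selected cutoff.

## Staging and association

Per-donor risk proportions feed four analyses:

* **Rule bands** (`stage_by_rule()`): proportion $< 0.10$ is ND, $[0.10,
  0.20]$ (closed band) preT2D, $> 0.20$ T2D. Band edges are configurable.
* **Margin classifier** (`fit_stage_classifier()`): a linear SVM per state
  pair on the single proportion feature, evaluated leave-one-donor-out;
  on one feature any maximum-margin classifier reduces to a threshold, so
  results are insensitive to SVM tuning. Held-out decision scores feed
  `roc_auc()`, whose AUC is the Mann–Whitney concordance probability with
  ties counted half. `bootstrap_auc_ci()` gives percentile intervals from
  2000 stratified (within-class) resamples by default.
* **Clinical association** (`pearson_assoc()`): pairwise-complete Pearson
  correlation with the two-sided $t$-transform p-value; the `n` actually
  used after dropping missing pairs is always reported.
* **Group comparison** (`group_compare()`): two-sided Wilcoxon rank-sum
  tests for the three state pairs, BH-adjusted. Exact enumeration is used
  when both groups have at most 8 donors and the proportions are tie-free;
  otherwise the tie-corrected normal approximation with continuity
  correction.

## Downstream contrasts

`pseudobulk_aggregate()` sums raw counts per donor and compartment
(risk/nonrisk), keeping a donor only when both compartments hold at least
`min_cells` (default 10) cells — a paired design, since both compartments
come from the same donors. `de_test()` is a minimal negative-binomial Wald
test: median-of-ratios size factors; per-gene method-of-moments dispersion
from Pearson residuals of a Poisson fit; a negative binomial GLM with
donor and compartment terms; BH across tested genes. It is deliberately
the minimal replicate-level NB test, not a reimplementation of a full
shrinkage-based DE engine, and the interface allows delegating to one.

`subtype_cluster()` is the field-standard PCA → kNN graph → Louvain chain,
with cluster ids reassigned by decreasing size and a pinned seed.
`risk_aggregation_dynamics()` tabulates per (cluster, stage) risk
fractions and a hypergeometric enrichment of risk cells per cluster within
each stage (BH across clusters) — showing where risk cells aggregate as
disease progresses. The hypergeometric construction is this package's
choice; descriptive fractions are always reported alongside it.

## The synthetic cohort simulator

`simulate_cohort()` emulates the mixture structure the framework assumes
and carries full ground truth:

* baseline gene log-means drawn once per run from $N(\log 0.5, 1)$;
* a per-donor, per-gene signature $N(0, \sigma_d)$ with $\sigma_d = 0.15$
  by default — a *donor* effect, deliberately gene-resolved so that a
  leaky model could exploit it, which is what the leakage guard tests
  (at $\sigma_d = 0.8$ with no disease effect, staging must stay at
  chance);
* each cell flagged risk with its donor state's probability (defaults
  0.05/0.15/0.30 along ND/preT2D/T2D, echoing the staging bands); risk
  status is i.i.d. within donor, so realized donor fractions vary
  binomially around the targets and are recorded exactly;
* risk cells have a single shared 100-gene program shifted by
  `effect_log2fc` $\times \log 2$ (default 1.0, i.e. 2-fold);
* counts drawn negative-binomially with mean $m$ and dispersion
  $\alpha = 0.5$ under the $\mathrm{Var} = m + \alpha m^2$ convention
  (conventions differ, so it is stated), with per-cell log-normal library
  factors (sd 0.3).

Defaults are 10 donors per state and 200 cells per donor over 1000 genes —
a desk-scale cohort on which the whole workflow, including
cross-validation and bootstrap, runs in well under five minutes.

What the simulator does **not** emulate: gene–gene correlation beyond the
shared program, batch effects beyond donor signatures, ambient RNA,
doublets, per-stage distinct programs, or realistic dropout structure.
Passing tests on simulated cohorts therefore show that the machinery
recovers a planted mixture signal under donor confounding and NB noise —
not that any particular real cohort will behave as cleanly.

## Numerical and statistical choices

* Strictly-greater threshold comparisons everywhere, so quantile calling
  at $q$ equals fixed calling at the computed quantile value.
* HVG ties break lexicographically by gene id; selection is deterministic
  and order-invariant.
* All randomness (fold shuffles, bootstrap, Louvain, simulation) is
  governed by explicit seeds, and seeded evaluation restores the caller's
  RNG state.
* Donor-level AUCs on 10 donors per state carry a sampling sd of roughly
  0.13; calibration checks on such quantities are therefore assessed on
  seed-averaged values rather than single draws.
* Degenerate inputs are handled explicitly: all-equal indexes warn and
  call nothing; all-zero genes are skipped and reported by `de_test()`;
  donors lacking cells of the analyzed type are omitted and logged.
* The run manifest records a wall-clock timestamp as provenance; the
  determinism guarantee (identical config, identical outputs, byte for
  byte) applies to all stage outputs, whose checksums the manifest holds.

## Problem sizes used by the test suite

The suite exercises the full default cohort (30 donors x 200 cells x 1000
genes) for end-to-end recovery, null, and leakage checks, and scaled-down
cohorts (e.g. 15 donors x 100 cells x 300 genes) for unit-level
properties; differential-expression calibration uses 20 donors x 100 cells
x 500 genes. These sizes are the package's chosen test conditions: large
enough for the donor-level statistics to be meaningful, small enough to
iterate on quickly.

## Known limitations

* The index is a probability under a specific model family; its absolute
  scale shifts with class balance and refinement, so fixed thresholds
  tuned on one cohort do not transfer automatically. Quantile or
  sliding-window calling is preferred for new cohorts.
* With very few donors per endpoint state, donor-grouped folds become
  coarse and the index noisy; `n_folds` must not exceed the smaller
  endpoint donor count.
* The DE test uses an unshrunk per-gene dispersion; at very small donor
  counts a shrinkage-based engine will be better powered.
* Staging decomposes the three-state problem into pairwise comparisons;
  no single multi-class classifier is fitted.
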