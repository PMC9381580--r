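---
title: "Methods: discovery and frozen validation of a pretreatment pCR signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovery and frozen validation of a pretreatment pCR signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pcrsig)
```

## Problem setting

Preoperative chemoradiotherapy for locally advanced rectal cancer produces a
pathological complete response (pCR) in a minority of patients. If pCR could
be predicted from a pretreatment biopsy, complete responders might be managed
with organ-preserving strategies. The clinically decisive error is a **false
positive** — calling pCR in a patient whose tumor would persist — so the
package's central operating point is *sensitivity at zero false-positive
rate* rather than accuracy or AUC.

`pcrsig` implements the full analysis chain: cohort simulation, quantile
normalization with a frozen reference, wrapper-based signature discovery,
a zero-training-FPR linear SVM, a normalization-free expression-ratio score,
and score-based survival stratification. This vignette documents the models,
the default parameters, and the numerical conventions.

## Data model and labels

An `expression_matrix()` stores log2-scale intensities for transcripts
(probe id + gene symbol) by samples. Response is recorded as a tumor
regression grade on a 0–100 percent scale (`trg_percent`); `derive_labels()`
maps it to classes:

* `positive` (pCR): regression ≥ `complete_threshold` (default 100),
* `negative` (poor response): regression < `poor_threshold` (default 45),
* `intermediate` otherwise; missing grades become `unknown`, with an
  `ordinal_map` fallback for cohorts graded on ordinal scales.

`extreme_responders()` restricts a cohort to the positive/negative extremes —
the discovery design — while full-range cohorts (including intermediates,
counted as non-pCR) are used only for frozen-model evaluation.

## Simulated cohorts

`generate_cohort()` draws gene baselines from Unif(6, 14) on the log2 scale
with i.i.d. Normal noise (`noise_sd`, default 1). The first `n_informative`
genes are shifted by `effect_size` in positive samples; under
`graded_effect = TRUE` the shift is proportional to `trg_percent / 100`, so
intermediates carry intermediate signal. `batch_shift` adds a constant to an
external cohort to emulate a platform/batch offset that normalization must
remove. `generate_validation_cohort()` reuses a reference cohort's gene
baselines so that frozen models are applicable across cohorts.
`generate_survival_cohort()` adds exponential survival times with hazard
$h_0 \exp(-\beta z)$ linked to a latent expression score $z$, and uniform
censoring calibrated (by `uniroot`) to a target censoring fraction.

The generator emulates effect sizes, tied ranks, batch offsets, graded
response, and score-linked hazards. It does **not** emulate gene–gene
correlation, probe-level artifacts, or non-exponential survival; conclusions
drawn from it are about the *procedures*, not about any real cohort.

## Quantile normalization with a frozen reference

`quantile_normalize()` maps each sample's empirical distribution onto the
per-rank mean of the column-sorted matrix. Ties receive the mean of the
reference values over the tied positions, so the operation is idempotent.
`reference_quantiles()` freezes that per-rank mean; `align_to_reference()`
then maps any sample — including a single new patient — onto the frozen
distribution by within-column rank replacement. Aligning a cohort to its own
reference reproduces ordinary quantile normalization exactly, which is the
package's internal consistency check.

## Classifier and the zero-FPR operating rule

`train_svm()` standardizes features, fits a linear soft-margin SVM
(cost default 1), and stores the model analytically as a weight vector and
offset so decision values are exact linear functions. The operating
threshold is set to the **maximum decision value among training negatives**
plus a tiny epsilon; calling pCR only strictly above it guarantees zero
false positives on the training data by construction. Sensitivity at zero
FPR uses the matching strict-greater convention: a positive counts only if
its score strictly exceeds every negative's score. `auc()` is the
Mann–Whitney statistic with ties counted 0.5, and `roc_curve()` emits one
point per distinct threshold so that the trapezoid integral equals the AUC
identically.

## Signature discovery by resampled hill climbing

`discover_signature()` repeats, for `n_repetitions` (default 500) stratified
3/4–1/4 splits of the extreme responders:

1. rank genes on the training split by Welch *t* (zero-variance genes are
   assigned p = 1 and flagged);
2. keep the top `pool_size` (default 100) as candidates;
3. grow a feature set greedily (`hill_climb_select()`), adding the candidate
   that most increases held-out sensitivity at zero FPR; ties prefer the
   earlier-ranked gene, and the search stops at the first non-improving step
   or when the objective reaches 1.

Genes selected significantly more often than chance form the signature. The
null is formalized as a binomial: under no signal each pool member is
selected with rate equal to (mean selected-set size)/(pool size), and
`selection_significance()` computes the exact upper-tail binomial p-value;
genes below `alpha` (Bonferroni over the pool) are retained. This is a
deliberately simple exchangeability null — it ignores correlation between
repetitions, so it is used for ranking and thresholding, not for inference
about real cohorts.

## Expression-ratio score

`compute_ratio_score()` evaluates
$\text{score} = \sum_{i \in \text{num}} E_i \,/\, \sum_{j \in \text{den}} E_j$
on **linear-scale** intensities (log2 input is exponentiated first; this is
the default because the score is a ratio of summed abundances, not of logs).
The score needs no normalization: it is exactly invariant to any positive
per-sample scale factor. `published_score()` freezes the 14-gene numerator
and 12-gene denominator of the reference formula, with the historical gene
symbols preserved verbatim and an alias map (`gene_alias_map()`) translating
them to current HGNC symbols when matching annotation.

`train_score_classifier()` searches numerator/denominator membership by
best-improvement local search over single gene add/remove toggles (the
denominator may never empty), from `n_restarts` (default 100) random
initializations, on one stratified 50/50 split; the restart with the best
held-out sensitivity at zero FPR wins (ties broken by training sensitivity,
then smaller set, then restart order). The search objective is monotone
non-decreasing along each ascent by construction.

## Survival analysis

`logrank_test()` implements the two-group log-rank statistic from the
hypergeometric moments at each distinct event time,
$\chi^2 = (O - E)^2 / V$, and `km_estimate()` the Kaplan–Meier
product-limit curve. `median_split()` dichotomizes a score at its median
(strictly greater = "high"). `run_prognosis_experiment()` chains score
computation, Spearman correlation with regression grade, the median split,
and log-rank tests per endpoint (OS, DFS). These are hand-rolled because
their arithmetic is part of the package's contract; the test suite
cross-checks them against `survival::survdiff` and other installed oracles.

## Workflow and leakage discipline

`run_discovery_experiment()` performs the full pipeline — extremes,
normalization, discovery, k-fold cross-validation, reference freezing, final
SVM — and only then applies the frozen model to full-range and external
cohorts. Validation data never influence training: the suite verifies that
every training artifact is byte-identical when validation labels are
permuted. All artifacts are deterministic JSON/TSV without timestamps, so
repeated runs are byte-reproducible.

## Numerical conventions, in one place

* Strict-greater tie handling for sensitivity at zero FPR and for the
  operating threshold; AUC ties count 0.5.
* Operating threshold epsilon: `max(1e-12, |max_neg| * 1e-12)` above the
  largest training-negative decision value.
* Quantile-normalization ties: mean of the reference over tied positions.
* Ratio score on linear scale by default; exact positive-scale invariance.
* Greedy searches are forward-only (discovery) or single-toggle
  best-improvement (score), with deterministic tie-breaks; "annealing"-style
  exploration is replaced by seeded random restarts.
* All randomness flows from a single user seed through `spawn_seeds()`
  substreams; seeds stay below 2^31.

## Limitations

The discovery null ignores inter-repetition correlation; the simulator omits
gene–gene correlation and non-proportional hazards; the SVM is linear only;
and the zero-FPR guarantee is structural on *training* data — on external
data it is an empirical property, reported as the false-positive count at
the frozen threshold.
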