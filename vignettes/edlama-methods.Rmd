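---
title: "Methods: annealed hyperparameter tuning and explainable LAMA prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annealed hyperparameter tuning and explainable LAMA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edlama)
```

## The problem

A small fraction of emergency-department (ED) patients leave against
medical advice (LAMA) — they depart during treatment, before a formal
discharge.  These departures carry elevated readmission and mortality
risk and are a recognized quality and revenue problem for EDs.  `edlama`
builds a classifier that, at triage time, scores each visit for LAMA
risk using only demographics, vital signs, the Emergency Severity Index
(ESI) acuity score, arrival-time features and front-end waiting time —
no diagnoses, so the prediction is available before a physician is
involved — and then explains the fitted model with additive per-feature
attributions.

Two properties shape everything downstream: the positive class is rare
(on the order of 0.66% of visits), and the deployment question is
explanatory as much as predictive.  The pipeline therefore couples class
rebalancing and stratification everywhere, uses AUC as the tuning
criterion, and treats attribution output as a first-class deliverable.

## The model and its tuning objective

The classifier is gradient-boosted trees (XGBoost) with the usual
additive-ensemble objective: a logistic loss plus a complexity penalty
$\gamma T + \tfrac{1}{2}\lambda\lVert w\rVert^2$ per tree, where $T$
counts leaves and $w$ are leaf weights.  Eight hyperparameters are
tuned: number of estimators, maximum depth, maximum delta step and
number of parallel trees on the integer grid $[1, 50]$; learning rate,
L1 and L2 penalties on $(0, 1]$; and $\gamma$ on $(0, 50]$
(`default_search_space()`).

The tuning objective is the mean AUC over stratified k-fold
cross-validation (k = 4 by default) of the training split.  Within each
fold, only the fitting portion is rebalanced — either random
oversampling (duplicating minority rows; no synthetic interpolation) or
random undersampling (thinning the majority) — and the held-out fold is
scored untouched.  This fold-interior rebalancing is deliberate: if
duplicated minority rows straddle a fold boundary, the duplicated
information leaks into validation and inflates AUC.  `audit_leakage()`
re-derives this from recorded row ids rather than trusting the code
path.

One consequence of rebalancing-by-duplication is that fold fixtures do
not depend on the candidate hyperparameters, so `make_cv_objective()`
freezes the fold assignment and the rebalanced fitting sets once per
run; every candidate is scored on identical data.

## The annealer

`atsa_optimize()` is an adaptive tabu simulated annealing (ATSA) search
over bounded mixed integer/float spaces, maximizing a black-box
objective.  Per temperature level it proposes up to `n_moves` Gaussian
neighbours of the current solution, accepts moves by the Metropolis rule
(always accept non-worsening moves; accept a worsening move of size
$\Delta < 0$ with probability $e^{\Delta/T}$), tracks the best-so-far
solution separately (strict improvement only, so ties keep the earlier
solution — reproducibility), and remembers evaluated candidates in a
fixed-capacity FIFO tabu list so the search does not revisit them.
Defaults: floor temperature 2, reheat multiplier $\beta = 2$, tabu
capacity 20, 300 levels × 8 moves, uniform initial solution, Gaussian
neighbourhood.

Several knobs of the schedule are genuinely open design choices, fixed
as follows and all exposed in `atsa_config()`:

* **Cooling.**  Geometric, $T \leftarrow \max(\alpha T, T_{\min})$ with
  $\alpha = 0.95$ and initial temperature 100 — standard simulated-
  annealing practice when only the floor and the reheat factor are
  prescribed.
* **Reheating.**  After 10 consecutive non-improving levels the
  temperature is multiplied by $\beta$ (capped at the initial
  temperature) and the stall counter resets.  Reheating is the escape
  mechanism from deep local basins; the cap prevents runaway heating.
* **Termination.**  The run always ends when the level budget is
  exhausted.  With reheating enabled a reheat is always eventually
  pending, so the floor is not a stopping state; with reheating disabled
  (`stall_reheat = Inf`) the run stops once cooling would cross the
  floor.
* **Step size.**  Neighbour proposals perturb every axis by a standard
  normal draw scaled by `step_scale` × the axis range, rounding integer
  axes half away from zero and clipping into bounds.  The default
  `step_scale = 0.1` makes one setting sensible across axes spanning
  $(0,1]$ and $[1,50]$; `step_scale = 1/(\text{range})` (per axis, a
  named vector is accepted) recovers a literal unit-variance step.  On
  very small integer grids the range-scaled default is too timid: on a
  5-point axis its step deviation is 0.4, almost every proposal rounds
  back to the current cell, and once the tabu list saturates the local
  neighbourhood the search stalls.  The discrete-space tests therefore
  use the literal unit-variance rule, which is also the update the
  framework's description prescribes.
* **Tabu identity.**  Float axes are quantized to 1/1000 of their range
  for the tabu key (exact float equality would make the list vacuous);
  integer axes match exactly.  A tabu-blocked proposal is regenerated up
  to 5 times, then the move is skipped — livelock protection on tiny
  spaces.

The objective is maximized directly (mean CV AUC); no sign flip is
exposed.

## Imputation and its validation

Missing values are imputed by K nearest neighbours: a missing cell is
replaced by the average of the K nearest rows' values in that column,
with distance computed as nan-aware Euclidean over standardized numeric
columns (dimensions missing in either row are skipped and the distance
rescaled by `p/shared`; binary indicator columns enter unscaled).
Binary cells are imputed by thresholding the neighbour mean at 0.5,
categorical cells by neighbour majority.  Ties in neighbour distance
break by row index, so imputation is deterministic.

K is not prescribed by the framework; the default is K = 5, and
`validate_imputation()` is exactly the instrument for choosing it
empirically: starting from the complete-case subset, 10% of cells are
withheld at random, re-imputed, and each numeric feature is scored by
MAPE over its withheld cells only,
$100 \cdot \mathrm{mean}(|x - \hat x|/|x|)$.  Withheld cells with a zero
original are excluded from the ratio and counted separately;
binary/categorical features are scored by mismatch rate instead (MAPE is
undefined for them).  Passing a vector of K values produces the report
across a K grid.

Two ordering statements conflict in the source framework (impute before
vs. after encoding); this package imputes on the raw table first and
encodes afterwards, which is well-defined for both numeric and
categorical columns.

Interpretation caveat for MAPE values: MAPE is relative to the cell's
own magnitude, so features whose values approach zero (age, or a
zero-anchored waiting time) produce large MAPEs even for accurate
imputations; the low-coefficient-of-variation vitals (temperature, O2
saturation) are the informative rows of the report.

## Encoding

Each c-level categorical becomes c−1 indicators: locations 10025, 10026,
15001 (reference 10001), male sex (reference female), non-Hispanic
ethnicity, and current/former/never smoker (reference: unknown status).
Repeated vital-sign readings (`pulse_rate_1`, `pulse_rate_2`, …) are
averaged; an `arrival_time` timestamp is reduced to month and hour; the
waiting time passes through in minutes; the disposition label is coded
LAMA = 1, SAT = 0.  Zip code is treated as numeric — a deliberate
simplification, the source data dictionary prints it as a numeric range
and treats it as a socio-economic proxy; a high-cardinality categorical
treatment is out of scope.

## Feature selection

`run_selectors()` wraps two estimators (a decision tree via `rpart`, a
random forest via `ranger`) with sequential forward and backward
selection, each step scored by the same stratified k-fold AUC criterion
used elsewhere.  SFS adds the best single feature until the improvement
is ≤ tolerance (default 1e-4 — below that the wrapper criterion is CV
noise); SBS removes the feature whose removal is least harmful until
every removal would worsen the criterion by more than the tolerance.
Ties break to the lowest column index, subset evaluations are cached,
and the five resulting data groups (DT_SFS, DT_SBS, RF_SFS, RF_SBS, and
all features) each get their own tuned model downstream.  The RF wrapper
uses 100 trees rather than ranger's default 500 — inside a greedy
wrapper × k folds the default multiplies runtime fivefold for no
measurable change in selected subsets at these data sizes; the value is
recorded in the run log.

## Attribution

`attribute()` returns exact per-instance additive attributions for the
tree ensemble (TreeSHAP-class backend), in log-odds margin units —
probability-space attributions would not be additive.  Local accuracy
(base value + per-feature scores = margin) is enforced by a scale-aware
guard: the backend accumulates in single precision, so the attainable
residual is about 1e-6 at unit margin scale and grows with the margin
magnitude and ensemble size.  The test suite verifies the strict 1e-6
contract on unit-scale models and verifies the attributions themselves
against an exhaustive subset-enumeration Shapley oracle on small trees.
`summarize_attributions()` reduces the score matrix to a global ranking
(mean |score|) and a per-feature direction (correlation of score with
feature value — the sign structure a beeswarm plot conveys);
`interactions()` produces the symmetric mean-|interaction| grid with
main effects on the diagonal.

## The synthetic cohort generator

No patient-level ED data ships with the package; `generate_visits()`
emulates the study population's schema and printed marginals so every
stage is testable end-to-end.  Numeric features are clipped normals
matching the printed mean, standard deviation and range (clipping, not
truncation, so boundary atoms exist but every value is in range; the
test oracles use the closed-form moments of the clipped distribution).
ESI is a discretized latent normal on {2..5}; arrival day/month/hour are
uniform; categorical mixes follow the printed percentages.  Pulse and
respiratory rate share a configurable latent correlation (default 0.4):
the printed marginals carry no joint structure, but neighbour-based
imputation is only meaningfully testable with some cross-feature
dependence.  Zip codes are drawn from a small fixed pool inside the
printed range.

The outcome is planted explicitly: a logistic model on the standardized
encoded features named in `effects`, with the intercept calibrated
numerically so the expected prevalence matches the configured target
(0.66% by default).  The generator returns the ground truth
(coefficients, intercept, and a Monte-Carlo estimate of the
Bayes-optimal AUC), which upper-bounds any fitted model's achievable
performance in tests.  What the generator does *not* emulate: the real
joint distribution of vitals and demographics, outcome-dependent
missingness patterns beyond the configurable class-conditional rates,
and any data-dependent numeric results of the source study — so a
passing test demonstrates that the machinery recovers known structure at
realistic prevalence, not that it reproduces any hospital's numbers.

## Problem sizes and numerical choices

The shipped verification runs use sizes chosen to exercise the
rare-class regime while remaining desk-scale: marginal and prevalence
checks at n = 1e5; the imputation MAPE protocol at 5,000 rows; the
end-to-end planted-signal run at n = 20,000 and prevalence 0.0066 with
4-fold CV, oversampling, and a 50-level × 8-move annealing budget over a
reduced four-axis space (estimators [1,30], depth [1,6], learning rate,
L2), with the tuning objective evaluated on a stratified 5,000-row
subsample of the training split and the final model refit on the full
split.  Tuning-on-a-subsample is a standard economy; the refit and all
reported test metrics use the full data.

Other numerical details: stratified splits guarantee both classes in
both partitions (the 80/20 split rounds per class, clamped so neither
partition is empty); `make_folds()` errors rather than silently
accepting a fold that lost the minority class; AUC uses midranks, so
ties count one half and a constant scorer yields exactly 0.5; the
classification threshold for accuracy/sensitivity/specificity defaults
to 0.5 and is exposed in the pipeline config; all xgboost fits are
single-threaded with a fixed seed, making every pipeline report
byte-reproducible for a given master seed.

## Model selection

Two selection rules coexist in the source framework's description: pick
the model with the highest mean cross-validated AUC, or the one with the
highest testing performance.  The pipeline computes the full model table
(data group × sampling mode), selects by mean CV AUC for the
explanation stage, and records both argmaxes in the manifest — neither
is silently preferred, and the table itself is always emitted.

## Known limitations

* The hyperparameter-tuning search space bounds the learning rate and
  the L1/L2 penalties by $(0,1]$, per the experimental-range table of
  the source framework, although tuned values above 1 appear in its
  reported results; the bound is honored here and the inconsistency is
  noted, not resolved.
* MAPE-based imputation validation is uninformative for near-zero-valued
  features (see above) and undefined for categoricals, where a mismatch
  rate is reported instead.
* The generator's independence structure (beyond the one configurable
  vitals correlation) makes KNN imputation look weaker than it would be
  on real, strongly correlated clinical data; the MAPE protocol is about
  the machinery, not an accuracy claim for any real cohort.
* At 0.66% prevalence a 4,000-row test partition contains only ~26
  positives, so test AUC for a signal-free model has a standard error
  near 0.05; chance-level results should be read with that width in
  mind.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  out_dir   = tempfile("edlama-run-"),
  generator = generator_config(5000, prevalence = 0.02,
                               effects = c(esi = 2.5, waiting_time = -1.5),
                               seed = 1),
  missing_rates = 0.05,
  atsa  = atsa_config(n_iterations = 25, seed = 1),
  space = default_search_space(),
  modes = "oversample", seed = 1)
res <- run_pipeline(cfg)
res$model_table
head(res$attribution)
```
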