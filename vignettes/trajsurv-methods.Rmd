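---
title: "Methods: longitudinal featurization for long-term survival prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal featurization for long-term survival prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trajsurv)
```

## The problem

Cohort studies measure risk factors repeatedly over many years, yet most
risk models consume a single snapshot. trajsurv compares, under identical
cross-validation, five ways of turning a participant x variable x visit
grid (the *data-collection window*) into inputs for survival models that
predict events over a subsequent *prediction window* anchored at the last
exam (a landmark analysis):

1. **Massive time-series feature extraction** — a fixed catalog of summary
   statistics per trajectory, pruned for missingness, constancy and
   Spearman correlation;
2. **Trajectory clustering** — per-variable cluster memberships from
   k-means on factor-selected summary measures;
3. **Last observed values** — the landmark exam only;
4. **Concatenation** — every (variable, visit) pair as its own predictor;
5. **Baseline reference** — the enrollment exam only (baseline carried
   forward).

Strategies feed a common fit/predict contract (`fit_survival_model()`,
`predict_survival()`) with three built-in families — Cox proportional
hazards, L1-penalized Cox, and a random survival forest — and any external
longitudinal model can participate by implementing the same contract (a
function from a feature table to risk scores suffices for the explainers).

## The synthetic cohort generator

Real long-running cardiovascular cohorts are access-controlled, so the
package ships a generator whose defaults emulate the structure of a
young-adult cohort followed through mid-life: 6 exams at years
0, 2, 5, 7, 10, 15 (the printed exam lists of such studies sometimes omit
an exam; we fix the six-exam calendar explicitly), 32 longitudinal
variables (20 continuous, 8 binary, 4 ordinal) plus age, sex and race
analogues, and a 17-year post-landmark prediction window with roughly a 5%
cumulative event rate and light exponential dropout
(`random_censor_rate = 0.008`/year).

Each variable follows a small number of latent trajectory classes
("low-stable", "high-increasing", "high-decreasing"; for binary variables,
state sequences such as always-smoker or quitting at year 7). Continuous
profiles are linear in time with per-person Gaussian random intercepts and
slopes; measurement noise is added per visit. Within-person visit-to-visit
noise is deliberately substantial for the signal-bearing variables (e.g.
SD 9 for systolic blood pressure, 14 for LDL against random-intercept SDs
of 5 and 8): single-visit measurements of blood pressure and lipids are
known to be noisy, and it is precisely this noise that gives
trajectory-averaging strategies their documented advantage over a single
landmark snapshot.

The hazard is a log-linear function of trajectory-derived truths — latent
per-person slopes (blood pressure, LDL, glucose, adiposity), mean levels
over the window, sustained-smoker class membership, and the fixed
demographics — each standardized by its approximate population moments so
a term with coefficient `c` contributes about `c^2` to the log-hazard
variance. Event times come from a Weibull process (`shape = 1` by default,
i.e. exponential with rate 0.0021/year, set so the default cohort lands at
~5% events by year 17); the exponential default keeps closed-form checks
of the event fraction available to the test-suite. Observed time is the
minimum of event, dropout, and the administrative horizon.

Missingness is MCAR at 2% of cells (first visit never masked), repaired by
last observation carried forward — matching the rare-missingness,
complete-case spirit of the emulated setting.

What the generator does *not* emulate: informative (outcome- or
level-dependent) missingness, irregular per-participant visit timing,
center or batch effects, competing risks, and nonlinear (curved or
seasonal) trajectories beyond an optional quadratic term. Tests passing on
this cohort therefore demonstrate the pipeline's correctness and its
qualitative behavior under known signal, not performance on any real
population.

## Featurization details

**Statistic catalog.** `ts_stat_catalog()` fixes 21 statistics per
trajectory: min, max, mean, median, variance, SD, first/last value, linear
trend intercept and slope (regression on visit years, not indices),
absolute energy, mean absolute change, c3 nonlinearity (lag 1),
time-reversal asymmetry (lag 1), autocorrelation (lags 1 and 2), a
sample-entropy variant (m = 2, r = 0.2 SD; `NA` when no template pairs
match, which the NA-pruning rule then removes), change-in-quantiles
(mean absolute consecutive change inside the interquartile corridor),
counts above/below the mean, and the longest strip above the mean. The
catalog is config-extensible; each entry is a pure function of
(series, times).

**Pruning.** `prune_features()` drops, in order: columns with any missing
value; columns with a single unique value; and, sweeping columns in
lexicographic (variable, statistic) order, the *later* column of any pair
with |Spearman rho| >= 0.95. Demographics are always kept and never enter
the sweep (trajectory features only are pruned). The operation is
idempotent, and the kept-earlier convention makes the pruned set
deterministic.

**Trajectory clustering.** `traj_summary_measures()` fixes 24 measures in
the families range/level/spread, total and relative change, linear fit
(slope, R^2), first- and second-difference summaries, rates of change, and
early-vs-late contrasts; zero-denominator measures take the sentinel 0.
Ratio measures have heavy tails when a series passes near zero, so each
measure is capped at its training 1%/99% quantiles before analysis (the
caps are part of the fitted state). "Factor analysis" is operationalized
as an eigen-decomposition of the measure correlation matrix, Kaiser rule
(eigenvalue > 1), varimax rotation when more than one factor survives, and
per-factor selection of the measure with the largest absolute loading.
The cluster count is a majority vote of four criteria — WSS elbow, mean
silhouette, Calinski-Harabasz, gap statistic — over k in 2..6, ties
broken toward smaller k; criteria are evaluated on a seeded subsample
(cap 1000) for large cohorts. Final k-means uses 10 restarts, and labels
are canonicalized by ascending within-cluster mean level so memberships
are reproducible across initializations. Out-of-fold participants are
assigned to the nearest training centroid in standardized selected-measure
space. Binary and ordinal trajectories run through the same measure
catalog; switch patterns surface through the change measures.

## Models

Proportional-hazards curves use the Breslow baseline cumulative hazard
estimated on the training fold; `exp(-H0(t) e^lp)` differs from the
product-limit estimator at second order, which the null-model test
acknowledges with a 0.01 tolerance. The L1 penalty is tuned inside the
training portion: by default with seeded, event-stratified 5-fold
cross-validated partial-likelihood deviance (a single small validation
split proved too noisy at ~100 events and occasionally selected the null
model; the CV plan still records a validation split for learners that
want one, and `validation_ids` switches to held-out partial-likelihood
selection), then the model is refitted at the chosen penalty on the full
training fold; the path is capped at 60 lambdas
down to 2% of lambda-max, which keeps the coordinate descent
well-conditioned on strongly correlated feature sets. Survival-forest
defaults (500 trees, node size 15, sqrt-p mtry, log-rank splitting) are
documented assumptions, overridable via `model_spec()`; forests run
single-threaded under a fixed seed so predictions are bit-reproducible.

## Evaluation

All headline metrics correct for censoring via inverse probability of
censoring weights from the Kaplan-Meier estimate of the censoring
distribution `G`: a subject failing at `t <= h` weighs `1/G(t-)`, a
subject event-free at `h` weighs `1/G(h)`, and subjects censored before
`h` drop out of the horizon-`h` contrast. The time-dependent AUC is the
weighted case/control ranking probability (ties half); the truncated
concordance weighs comparable pairs by `1/G(T_i-)^2` (Harrell's unweighted
C is deliberately not the headline metric); the Brier score is the
weighted squared error of the predicted survival probability. The
integrated AUC weights per-horizon AUCs by the Kaplan-Meier event-density
mass of each grid interval, renormalized over defined horizons; the
default grid is the integer years 1..17 ("last AUC" at 17). When `G`
reaches zero before a requested horizon the metric returns a documented
`NA` sentinel rather than an extrapolated value. Threshold metrics
(sensitivity, specificity, PPV, NPV, MCC) are reported at the cutoff
maximizing the IPCW-weighted F1 over observed risk values, ties resolved
toward the lower cutoff.

Cross-validation is 5-fold x 2 repeats, stratified by event status, with a
stratified validation split inside each training portion (60/20/20
overall). Featurizer state — the pruning set, selected measures,
winsorization caps, centroids, and the lasso penalty — is fitted on
training ids only and applied unchanged to the test fold; the test suite
asserts this by recomputing the state from a training-only cohort.

Summaries report the fold mean with a seeded 95% percentile bootstrap
interval obtained by resampling the per-fold metric values (1000
resamples). We bootstrap fold-level values rather than pooled test-set
predictions because the fold is the unit of the resampling design; pooling
predictions across folds would mix models fitted on different training
sets into a single pseudo-model.

## Explanation suite

*Permutation importance* permutes one column at a time and reports the
mean loss increase, normalized by the maximum. The default loss, here and
for the temporal explainer, is one minus the truncated concordance at the
last horizon — the loss the benchmark itself ranks models by — and is
configurable because no single loss is canonical.

*Sampling Shapley* draws feature orderings, imputes absent features from a
sampled background row, and averages marginal contributions to the
predicted risk at a fixed horizon (risk-at-horizon, not expected survival
time, is the explained quantity). Efficiency is enforced post hoc by
spreading the residual equally; both the raw and adjusted values are
reported, and the raw residual concentrates at `O(1/sqrt(n_samples))`. The
background defaults to (a subsample of) the training table; cap it at ~100
rows for expensive models.

*Cluster partial dependence* replaces every participant's membership for
one variable with cluster `c` and averages the predicted curves.

*Temporal-window importance* treats per-visit models: overall importance
permutes a variable's whole series across participants (series intact
within participant); the reported window is the smallest contiguous visit
range whose permutation captures at least `1 - w` of the overall
importance (`w = 0.1`, i.e. 90%), searched by increasing width then left
index so ties resolve toward the earliest window — early-life exposure
windows are the interesting ones. Whether ordering matters inside the
window is a permutation test of within-participant shuffling (the exact
hierarchical FDR testing of the original temporal-importance method is
simplified to per-variable permutation p-values with Benjamini-Hochberg
correction across variables — a documented deviation); single-visit
windows are trivially order-free. Windows are only reported above a
normalized-importance floor (default 0.05) since for null variables the
"smallest window capturing 90% of nothing" is noise. Per-visit single-cell
permutations populate the variable x visit heatmap, drawn in ordered
quartile bins (darker = more important). Defaults are 100 permutations and
`w = 0.1`.

Note that a variable whose per-visit contributions are unequal (e.g. a
slope functional over unevenly spaced visits, where endpoints dominate)
can legitimately receive a proper sub-window; the "full window" intuition
applies when contributions are balanced.

## Problem sizes and numerical choices

The test-suite exercises the comparative claim on the default cohort
(n = 2000, ~5% events, 5x2 CV) with the penalized Cox family — chosen for
the benchmark loop because its fit cost allows the full 40-cell grid to
run quickly at this scale; the survival forest is exercised on the
smaller model-contract tests. Metric identities are verified on 50 random
uncensored instances (n <= 60) against brute-force pairwise oracles at
1e-10; Shapley sampling is compared with exact subset enumeration on
6-feature models at 0.01. Clustering recovery uses the three-class
low-stable / high-decreasing / high-increasing geometry. At ~110 events,
the concatenation and last-visit strategies are near-equivalent for a
penalized linear learner (the penalty tends to select the landmark visit
out of the concatenated matrix); the gap between trajectory-based and
baseline-only inputs is the robust, reproducible contrast.

## Limitations

The generator's simplifications (listed above) bound what green tests
mean; explanation outputs describe model behavior, not causal structure;
competing risks, recurrent events and dynamic (post-landmark) prediction
are out of scope; and the trajectory-clustering step inherits the known
fragility of one-measure-per-factor selection: when class structure is
colinear across measures, or when Kaiser retention keeps factors driven
purely by measurement noise (the first- and second-difference spread
measures), the selected representatives dilute the informative
dimensions and the criterion vote for k becomes unstable under
substantial noise. The winsorization caps mitigate but do not remove
this.
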