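# trajsurv

**Survival prediction from multivariate longitudinal trajectories — a
comparative featurization framework with censoring-adjusted evaluation and
model-agnostic explanation.**

Long-running cohort studies measure dozens of risk factors at repeated
exams, yet most clinical risk scores use a single visit. For an
epidemiologist or biostatistician asking *"what does the trajectory add?"*,
trajsurv provides the full experimental bench: simulate (or load) a
participant × variable × visit grid, convert it to model-ready tables under
five featurization strategies, fit standard survival learners, compare them
with censoring-adjusted metrics under repeated stratified cross-validation,
and explain the fitted models.

## What it implements

**Featurization strategies** (all take a cohort, return a tidy feature
table with column provenance):

| Strategy | Function | Inputs per participant |
|---|---|---|
| Time-series massive feature extraction | `extract_ts_features()` + `prune_features()` | ~21 statistics × variable, Spearman-pruned at ρ ≥ 0.95 |
| Trajectory clustering | `featurize_clusters()` | one k-means cluster membership per variable (24 summary measures → factor selection → criterion-voted k) |
| Last observed values | `featurize_cross_sectional(cohort, "last")` | landmark-exam values |
| Concatenation | `featurize_concatenated()` | every (variable, visit) pair (e.g. 32 × 6 = 192 columns) |
| Baseline reference | `featurize_cross_sectional(cohort, "first")` | enrollment-exam values |

**Models.** Cox proportional hazards, L1-penalized Cox (penalty tuned by
cross-validated partial likelihood), and a random survival forest, behind
one fit/predict contract producing per-participant survival curves
S(t | x); risk at horizon *t* is 1 − S(t | x). Any external model can plug
in by honoring the same contract.

**Evaluation.** All headline metrics use inverse probability of censoring
weighting (IPCW) with G, the Kaplan–Meier estimate of the censoring
distribution. At horizon *h*:

- time-dependent AUC(h) = weighted P(risk_case > risk_control), cases
  (T ≤ h, δ = 1) weighted 1/G(T−), controls (event-free through h)
  weighted 1/G(h−);
- truncated concordance C(τ) over comparable pairs (T_i < T_j, δ_i = 1,
  T_i < τ) with weights 1/G(T_i−)² (Harrell's unweighted C is deliberately
  not used);
- Brier(h) = n⁻¹ Σ [ S(h|x)² 1(T≤h, δ=1)/G(T−) + (1−S(h|x))² 1(event-free
  at h)/G(h−) ];
- iAUC = Σ_k w_k AUC(t_k) with w_k ∝ the KM event-density mass of each
  grid interval;
- sensitivity/specificity/PPV/NPV/MCC at the F1-maximizing cutoff.

The harness (`make_cv_plan()`, `run_benchmark()`) is 5-fold × 2-repeat
stratified cross-validation; all featurizer state is fitted on training
folds only. Summaries report fold means with seeded 95% percentile
bootstrap intervals.

**Explanation.** `permutation_importance()`, `shapley_sampling()`
(permutation-sampling Shapley with exact-efficiency adjustment),
`partial_dependence_clusters()`, and `time_importance()` — a temporal
permutation procedure reporting, per variable, overall importance, the
smallest contiguous visit window carrying ≥ 90% of it, whether
within-window temporal ordering matters, and a variable × visit heatmap.

**Synthetic cohort.** `cohort_config()` + `simulate_cohort()` generate a
CARDIA-like structure: 6 exams over 15 years, 32 longitudinal + 3 fixed
variables with latent trajectory classes ("low-stable",
"high-increasing", quit-smoking-at-year-7, ...), and a 17-year
time-to-event outcome (~5% events) whose hazard is driven by the latent
trajectory slopes and levels — so ground truth is available for every
downstream test.

## Worked example

```r
library(trajsurv)

cfg <- cohort_config(seed = 42)          # default: n = 2000
sim <- simulate_cohort(cfg)
sim$cohort
#> <longitudinal_cohort> 2000 participants, 32 longitudinal variables, 6 visits (0, 2, 5, 7, 10, 15)
#>   fixed covariates: age, sex_male, race_black
#>   latent truth attached
sum(sim$outcome$event)                   # 107 events (5.3%)

plan  <- make_cv_plan(sim$outcome, folds = 5, repeats = 2, seed = 42)
bench <- run_benchmark(
  sim$cohort, sim$outcome,
  strategies = c("ts_features", "concatenated", "last_visit", "baseline"),
  specs = list(lasso_cox = model_spec("lasso_cox", seed = 42)),
  plan = plan, horizons = 1:17)
comparison_table(summarize_benchmark(bench, seed = 42))
#> # A tibble: 4 x 5
#>   strategy     model     last_auc             cindex               iauc
#> 1 baseline     lasso_cox 0.611 (0.569, 0.651) 0.606 (0.564, 0.647) 0.555 (0.505, 0.595)
#> 2 concatenated lasso_cox 0.716 (0.685, 0.748) 0.707 (0.681, 0.740) 0.680 (0.639, 0.720)
#> 3 last_visit   lasso_cox 0.725 (0.696, 0.757) 0.716 (0.689, 0.750) 0.690 (0.642, 0.734)
#> 4 ts_features  lasso_cox 0.726 (0.696, 0.755) 0.717 (0.690, 0.747) 0.684 (0.642, 0.720)
```

Each cell is the mean over the 10 test folds with its 95% bootstrap
interval. On this synthetic cohort the trajectory-based strategies beat
the enrollment-only baseline by ~0.11 in truncated C-index (0.72 vs
0.61) — the event hazard is driven by trajectory slopes, which a single
baseline snapshot cannot see — while the last-observed landmark values
recover most of the discrimination at this sample size (~110 events).
`plot_auc_curves()`, `autoplot()` on curves, importance, Shapley, partial
dependence and temporal-heatmap objects produce the corresponding
figures, and `run_pipeline()` drives the whole loop from a YAML config
(see `inst/extdata/example-config.yaml`), writing per-fold metrics,
summary tables, rankings and a manifest.

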