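# Example pipeline configuration for run_pipeline() /
# read_pipeline_config(). Top-level keys are pipeline_config() arguments;
# cohort keys override cohort_config() defaults.
cohort:
  n_participants: 800
  admin_censor_years: 17.0
  missing_rate: 0.02
strategies:
  - ts_features
  - last_visit
  - baseline
models:
  lasso_cox:
    family: lasso_cox
  cox:
    family: coxph
folds: 5
repeats: 2
horizons: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17]
explain:
  importance: true
  time: false
  pdp: false
seed: 7
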