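test_that("folds are stratified by event and partition the cohort", {
  out <- tibble::tibble(participant_id = sprintf("P%03d", 1:100),
                        time_years = runif(100, 1, 17),
                        event = c(rep(1L, 10), rep(0L, 90)))
  plan <- make_cv_plan(out, folds = 5, repeats = 2, seed = 4)
  for (r in 1:2) {
    a <- plan$assignment[plan$assignment$rep == r, ]
    # partition: every id in exactly one test fold
    expect_setequal(a$participant_id, out$participant_id)
    expect_equal(nrow(a), 100)
    # exactly 2 events and 18 non-events per fold
    ev <- out$event[match(a$participant_id, out$participant_id)]
    counts <- table(a$fold, ev)
    expect_true(all(counts[, "1"] == 2))
    expect_true(all(counts[, "0"] == 18))
  }
  # repeats differ, same seed reproduces both
  a1 <- plan$assignment[plan$assignment$rep == 1, ]
  a2 <- plan$assignment[plan$assignment$rep == 2, ]
  expect_false(identical(
    a1$fold[match(out$participant_id, a1$participant_id)],
    a2$fold[match(out$participant_id, a2$participant_id)]))
  plan2 <- make_cv_plan(out, folds = 5, repeats = 2, seed = 4)
  expect_identical(plan$assignment, plan2$assignment)
  expect_identical(plan$validation, plan2$validation)
})

test_that("validation splits stay inside the training portion", {
  out <- tibble::tibble(participant_id = sprintf("P%03d", 1:80),
                        time_years = runif(80, 1, 17),
                        event = rbinom(80, 1, 0.2))
  plan <- make_cv_plan(out, folds = 4, repeats = 1, seed = 9)
  for (f in 1:4) {
    ids <- trajsurv:::plan_ids(plan, 1, f)
    expect_length(intersect(ids$validation, ids$test), 0)
    expect_true(all(ids$validation %in% ids$train))
  }
})

test_that("plans with fewer events than folds are refused", {
  out <- tibble::tibble(participant_id = letters[1:10],
                        time_years = 1:10,
                        event = c(1L, 1L, rep(0L, 8)))
  expect_error(make_cv_plan(out, folds = 5), "events")
})

test_that("benchmark bookkeeping: one row per metric, fold and combination", {
  cfg <- small_test_config(n = 200, seed = 23)
  sim <- simulate_cohort(cfg)
  plan <- make_cv_plan(sim$outcome, folds = 2, repeats = 1, seed = 23)
  bench <- run_benchmark(sim$cohort, sim$outcome,
                         strategies = "last_visit",
                         specs = list(cox = model_spec("coxph")),
                         plan = plan, horizons = c(5, 10))
  expect_equal(nrow(bench$errors), 0)
  m <- bench$metrics
  expect_equal(sum(m$metric == "auc" & m$horizon == 5), 2)
  expect_equal(sum(m$metric == "cindex"), 2)
  expect_equal(sum(m$metric == "iauc"), 2)
  expect_setequal(unique(m$fold), 1:2)
})

test_that("featurizer state is a function of training ids only", {
  cfg <- small_test_config(n = 120, seed = 24)
  sim <- simulate_cohort(cfg)
  train <- sim$cohort$ids[1:80]
  ts_pre <- extract_ts_features(sim$cohort)
  a <- featurize_strategy(sim$cohort, "ts_features", train_ids = train,
                          ts_features = ts_pre)
  # recomputing from a cohort restricted to training ids gives the same
  # pruning set
  sub_long <- as_tibble(sim$cohort) |>
    dplyr::filter(.data$participant_id %in% train)
  sub <- as_longitudinal_cohort(
    sub_long, fixed = sim$cohort$fixed[
      match(train, sim$cohort$fixed$participant_id), ],
    visit_years = sim$cohort$visit_years)
  b <- prune_features(extract_ts_features(sub))
  expect_setequal(names(a), names(b))
  # cluster centroids likewise depend on training ids only
  ftc <- featurize_strategy(sim$cohort, "clusters", train_ids = train,
                            cluster_args = list(
                              k_range = 2:3, seed = 5,
                              criteria = c("wss", "silhouette", "ch")))
  mods <- attr(ftc, "cluster_models")
  direct <- cluster_trajectories(sim$cohort, "a", ids = train,
                                 k_range = 2:3, seed = 5,
                                 criteria = c("wss", "silhouette", "ch"))
  expect_equal(mods$a$centroids, direct$centroids)
  expect_setequal(mods$a$memberships$participant_id, train)
})

test_that("shuffled outcomes drive the AUC to chance", {
  cfg <- small_test_config(n = 400, seed = 25)
  cfg$baseline_rate <- 0.03
  sim <- simulate_cohort(cfg)
  set.seed(1)
  shuffled <- sim$outcome
  perm <- sample(nrow(shuffled))
  shuffled$time_years <- shuffled$time_years[perm]
  shuffled$event <- shuffled$event[perm]
  plan <- make_cv_plan(shuffled, folds = 2, repeats = 1, seed = 25)
  bench <- run_benchmark(sim$cohort, shuffled,
                         strategies = "last_visit",
                         specs = list(cox = model_spec("coxph")),
                         plan = plan, horizons = c(8, 12, 16))
  aucs <- bench$metrics$value[bench$metrics$metric == "auc"]
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.12)
})

test_that("bootstrap intervals contain the point estimate and tighten with folds", {
  set.seed(31)
  vals5 <- tibble::tibble(rep = 1, fold = 1:5, strategy = "s", model = "m",
                          metric = "cindex", horizon = NA_real_,
                          value = rnorm(5, 0.75, 0.05))
  vals20 <- tibble::tibble(rep = 1, fold = 1:20, strategy = "s",
                           model = "m", metric = "cindex",
                           horizon = NA_real_,
                           value = rnorm(20, 0.75, 0.05))
  s5 <- summarize_benchmark(vals5, seed = 2)
  s20 <- summarize_benchmark(vals20, seed = 2)
  expect_true(s5$lo <= s5$mean && s5$mean <= s5$hi)
  expect_lt(s20$hi - s20$lo, s5$hi - s5$lo)
})

test_that("comparison report ranks by iAUC, breaks ties by name, flags failures", {
  mk <- function(strategy, vals) tibble::tibble(
    rep = 1, fold = seq_along(vals), strategy = strategy, model = "m",
    metric = "iauc", horizon = NA_real_, value = vals)
  metrics <- dplyr::bind_rows(mk("alpha", rep(0.75, 4)),
                              mk("beta", rep(0.80, 4)),
                              mk("gamma", rep(0.75, 4)))
  bench <- structure(list(metrics = metrics,
                          errors = tibble::tibble(
                            rep = 1, fold = 1, strategy = "delta",
                            model = "m", error = "boom")),
                     class = "benchmark_result")
  rep_ <- compare_report(bench)
  expect_equal(rep_$strategy[1:3], c("beta", "alpha", "gamma"))
  expect_equal(rep_$iauc[1] - rep_$iauc[2], 0.05)
  drow <- rep_[rep_$strategy == "delta", ]
  expect_false(drow$converged)
  expect_true(is.na(drow$rank))
})
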