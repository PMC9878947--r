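#' Build a repeated stratified cross-validation plan
#'
#' Each repeat partitions the cohort into `folds` test folds, stratified by
#' event status so the event:non-event ratio is preserved across folds (up
#' to one participant). Within each training portion a stratified
#' validation split is additionally recorded (60/20/20
#' train/validation/test by default) for learners tuned on an explicit
#' held-out split; the built-in penalized Cox default instead tunes by
#' seeded cross-validation inside the training portion, which is far less
#' noisy at low event counts.
#'
#' @param outcome Tibble with `participant_id`, `time_years`, `event`.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 2).
#' @param seed Integer seed.
#' @param validation_frac Fraction of each training portion reserved for
#'   validation (default 0.25, i.e. 20% of the cohort).
#' @return A `cv_plan` with tibbles `assignment`
#'   (`rep`, `fold`, `participant_id`) and `validation`.
#' @export
make_cv_plan <- function(outcome, folds = 5, repeats = 2, seed = 1L,
                         validation_frac = 0.25) {
  n_event <- sum(outcome$event == 1)
  if (n_event < folds) stop("fewer events (", n_event, ") than folds",
                            call. = FALSE)
  set.seed(stage_seed(seed, "cv"))
  assign_rep <- function(r) {
    fold_of <- do.call(c, unname(
      lapply(split(outcome$participant_id, outcome$event),
             function(idset) {
               sh <- sample(idset)
               setNames(rep_len(sample(folds), length(sh)), sh)
             })))
    tibble::tibble(rep = r, fold = as.integer(fold_of),
                   participant_id = names(fold_of))
  }
  assignment <- dplyr::bind_rows(lapply(seq_len(repeats), assign_rep))
  validation <- dplyr::bind_rows(lapply(seq_len(repeats), function(r) {
    dplyr::bind_rows(lapply(seq_len(folds), function(f) {
      a <- assignment[assignment$rep == r, ]
      train_ids <- a$participant_id[a$fold != f]
      ev <- outcome$event[match(train_ids, outcome$participant_id)]
      val <- unlist(lapply(split(train_ids, ev), function(g) {
        sample(g, max(1, round(length(g) * validation_frac)))
      }), use.names = FALSE)
      tibble::tibble(rep = r, fold = f, participant_id = val)
    }))
  }))
  structure(list(assignment = assignment, validation = validation,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", x$folds, "-fold x ", x$repeats,
      " repeats, stratified by event (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

plan_ids <- function(plan, r, f) {
  a <- plan$assignment[plan$assignment$rep == r, ]
  v <- plan$validation[plan$validation$rep == r &
                         plan$validation$fold == f, ]
  list(test = a$participant_id[a$fold == f],
       train = a$participant_id[a$fold != f],
       validation = v$participant_id)
}

score_fold <- function(curves, outcome_test, horizons) {
  G <- censoring_km(outcome_test)
  aucs <- vapply(horizons, function(h) {
    time_dependent_auc(risk_at(curves, h), outcome_test, h, G)
  }, 1)
  last_h <- max(horizons)
  risk_last <- risk_at(curves, last_h)
  rows <- tibble::tibble(metric = "auc", horizon = horizons, value = aucs)
  rows <- dplyr::bind_rows(
    rows,
    tibble::tibble(
      metric = c("iauc", "cindex", "brier", "ibs"),
      horizon = NA_real_,
      value = c(integrated_auc(aucs, horizons, outcome_test),
                truncated_cindex(risk_last, outcome_test, last_h, G),
                brier_score(curves, outcome_test, last_h, G),
                integrated_brier(curves, outcome_test, horizons, G))))
  cls <- classification_at_horizon(risk_last, outcome_test, last_h, G)
  dplyr::bind_rows(
    rows,
    tidyr::pivot_longer(cls, dplyr::everything(), names_to = "metric",
                        values_to = "value") |>
      dplyr::mutate(horizon = NA_real_))
}

#' Run the strategy x model benchmark under cross-validation
#'
#' For every (strategy, model family, fold, repeat) cell: featurize with
#' state fitted on training ids only (pruning sets and cluster centroids
#' never see the test fold), fit the model (penalty tuned inside the
#' training portion), predict survival on the test fold, and score the
#' censoring-adjusted metrics at all horizons. Failing cells are logged and
#' skipped, mirroring a "did not converge" report row.
#'
#' @param cohort A complete `longitudinal_cohort`.
#' @param outcome Outcome tibble.
#' @param strategies Character vector from [strategy_names()].
#' @param specs Named list of [model_spec()]s (names label the model).
#' @param plan A [make_cv_plan()].
#' @param horizons Evaluation horizons in years (default `1:17`).
#' @param rho_max,cluster_args Passed to [featurize_strategy()].
#' @return A `benchmark_result`: per-fold metric tibble (`rep`, `fold`,
#'   `strategy`, `model`, `metric`, `horizon`, `value`) plus an error log.
#' @export
run_benchmark <- function(cohort, outcome, strategies = strategy_names(),
                          specs = list(lasso_cox =
                                         model_spec("lasso_cox")),
                          plan = make_cv_plan(outcome),
                          horizons = 1:17, rho_max = 0.95,
                          cluster_args = list()) {
  ts_pre <- if ("ts_features" %in% strategies) {
    extract_ts_features(cohort)
  }
  metric_rows <- list()
  error_rows <- list()
  for (r in seq_len(plan$repeats)) {
    for (f in seq_len(plan$folds)) {
      ids <- plan_ids(plan, r, f)
      out_test <- outcome[match(ids$test, outcome$participant_id), ]
      for (strat in strategies) {
        ft_all <- tryCatch(
          featurize_strategy(cohort, strat, train_ids = ids$train,
                             ts_features = ts_pre, rho_max = rho_max,
                             cluster_args = cluster_args),
          error = function(e) e)
        if (inherits(ft_all, "error")) {
          error_rows[[length(error_rows) + 1]] <- tibble::tibble(
            rep = r, fold = f, strategy = strat, model = NA_character_,
            error = conditionMessage(ft_all))
          next
        }
        for (mn in names(specs)) {
          res <- tryCatch({
            fit <- fit_survival_model(ft_rows(ft_all, ids$train), outcome,
                                      specs[[mn]])
            curves <- predict_survival(fit, ft_rows(ft_all, ids$test),
                                       horizons)
            score_fold(curves, out_test, horizons)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            error_rows[[length(error_rows) + 1]] <- tibble::tibble(
              rep = r, fold = f, strategy = strat, model = mn,
              error = conditionMessage(res))
          } else {
            metric_rows[[length(metric_rows) + 1]] <- dplyr::mutate(
              res, rep = r, fold = f, strategy = strat, model = mn,
              .before = 1)
          }
        }
      }
    }
  }
  structure(list(metrics = dplyr::bind_rows(metric_rows),
                 errors = dplyr::bind_rows(error_rows),
                 horizons = horizons, plan = plan),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ",
      length(unique(x$metrics$strategy)), " strategies x ",
      length(unique(x$metrics$model)), " models, ",
      x$plan$folds, "-fold x ", x$plan$repeats, " CV\n", sep = "")
  if (nrow(x$errors)) cat("  ", nrow(x$errors), " failed cells\n", sep = "")
  invisible(x)
}

#' Aggregate per-fold metrics into mean and bootstrap interval
#'
#' Mean over test folds plus a seeded 95% percentile bootstrap interval of
#' the mean, resampling fold-level metric values (1000 resamples).
#'
#' @param result A `benchmark_result` (or its `$metrics` tibble).
#' @param n_boot Bootstrap resamples.
#' @param conf Interval coverage.
#' @param seed Integer seed.
#' @return Tibble with `strategy`, `model`, `metric`, `horizon`, `mean`,
#'   `lo`, `hi`, `n_folds`.
#' @export
summarize_benchmark <- function(result, n_boot = 1000, conf = 0.95,
                                seed = 1L) {
  metrics <- if (inherits(result, "benchmark_result")) result$metrics
             else result
  set.seed(stage_seed(seed, "boot"))
  alpha <- (1 - conf) / 2
  metrics |>
    dplyr::group_by(.data$strategy, .data$model, .data$metric,
                    .data$horizon) |>
    dplyr::group_modify(function(g, key) {
      v <- g$value[!is.na(g$value)]
      if (length(v) == 0) {
        return(tibble::tibble(n_folds = 0L, mean = NA_real_,
                              lo = NA_real_, hi = NA_real_))
      }
      if (length(v) == 1) {
        return(tibble::tibble(n_folds = 1L, mean = v,
                              lo = v, hi = v))
      }
      bm <- vapply(seq_len(n_boot),
                   function(b) mean(sample(v, replace = TRUE)), 1)
      tibble::tibble(n_folds = length(v), mean = mean(v),
                     lo = quantile(bm, alpha, names = FALSE),
                     hi = quantile(bm, 1 - alpha, names = FALSE))
    }) |>
    dplyr::ungroup()
}

#' Comparison table in the headline-report shape
#'
#' One row per (strategy, model) with mean and 95% bootstrap interval of
#' the integrated AUC, truncated C-index and AUC at the last horizon.
#'
#' @param summary Output of [summarize_benchmark()].
#' @return Tibble with formatted `iauc`, `cindex`, `last_auc` columns.
#' @export
comparison_table <- function(summary) {
  last_h <- max(summary$horizon[summary$metric == "auc"], na.rm = TRUE)
  fmt <- function(m, lo, hi) {
    ifelse(is.na(m), "Did not converge",
           sprintf("%.3f (%.3f, %.3f)", m, lo, hi))
  }
  keep <- summary |>
    dplyr::filter(.data$metric %in% c("iauc", "cindex") |
                    (.data$metric == "auc" & .data$horizon == last_h)) |>
    dplyr::mutate(metric = ifelse(.data$metric == "auc", "last_auc",
                                  .data$metric),
                  cell = fmt(.data$mean, .data$lo, .data$hi))
  keep |>
    dplyr::select("strategy", "model", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell") |>
    dplyr::arrange(.data$strategy, .data$model)
}

#' Rank strategies by integrated AUC
#'
#' Ranks (strategy, model) rows by mean integrated AUC, flags interval
#' overlap with the top row, and lists failed combinations as
#' non-convergent (excluded from the ranking). Equal means are ordered
#' stably by strategy then model name.
#'
#' @param result A `benchmark_result`.
#' @param summary Optional precomputed [summarize_benchmark()] output.
#' @return Tibble with `rank`, `strategy`, `model`, `iauc`, `lo`, `hi`,
#'   `overlaps_best`, `converged`.
#' @export
compare_report <- function(result, summary = NULL) {
  summary <- summary %||% summarize_benchmark(result)
  ia <- summary |>
    dplyr::filter(.data$metric == "iauc") |>
    dplyr::arrange(dplyr::desc(.data$mean), .data$strategy, .data$model)
  failed <- if (inherits(result, "benchmark_result") &&
                nrow(result$errors)) {
    result$errors |>
      dplyr::distinct(.data$strategy, .data$model) |>
      dplyr::anti_join(ia, by = c("strategy", "model"))
  } else {
    tibble::tibble(strategy = character(), model = character())
  }
  ranked <- ia |>
    dplyr::mutate(rank = dplyr::row_number(),
                  overlaps_best = .data$lo <= ia$hi[1] &
                    .data$hi >= ia$lo[1],
                  converged = TRUE) |>
    dplyr::select("rank", "strategy", "model", iauc = "mean", "lo", "hi",
                  "overlaps_best", "converged")
  if (nrow(failed)) {
    ranked <- dplyr::bind_rows(
      ranked,
      dplyr::mutate(failed, rank = NA_integer_, iauc = NA_real_,
                    lo = NA_real_, hi = NA_real_, overlaps_best = FALSE,
                    converged = FALSE))
  }
  ranked
}
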