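#' Cross-sectional featurization (last-observed and baseline reference)
#'
#' One column per longitudinal variable holding its value at a single visit
#' of the data-collection window, plus the fixed covariates. `visit =
#' "last"` is the last-observed-values strategy (a single landmark
#' analysis); `visit = "first"` is the baseline-carried-forward reference.
#'
#' @param cohort A complete `longitudinal_cohort`.
#' @param visit `"first"`, `"last"`, or a 1-based visit index.
#' @return A [feature_table()] whose provenance records the visit year.
#' @export
featurize_cross_sectional <- function(cohort, visit = "last") {
  p <- length(cohort$visit_years)
  j <- if (identical(visit, "first")) 1L
       else if (identical(visit, "last")) p
       else as.integer(visit)
  if (is.na(j) || j < 1 || j > p) {
    stop("visit out of range: ", visit, call. = FALSE)
  }
  yr <- cohort$visit_years[j]
  out <- list(participant_id = cohort$ids)
  pv <- list()
  for (v in names(cohort$grids)) {
    cn <- paste0(v, "__y", yr)
    out[[cn]] <- as.numeric(cohort$grids[[v]][, j])
    pv[[cn]] <- tibble::tibble(column = cn, source_variable = v,
                               statistic = paste0("visit_", yr),
                               visit_year = yr)
  }
  ft <- feature_table(tibble::as_tibble(out), dplyr::bind_rows(pv))
  append_fixed(ft, cohort)
}

#' Per-visit concatenation featurization
#'
#' Treats every (variable, visit) pair as its own predictor: a cohort with
#' `v` longitudinal variables and `p` visits yields `v * p` trajectory
#' columns plus the fixed covariates. Column provenance records the visit
#' year, which is what the temporal-window explainer consumes.
#'
#' @param cohort A complete `longitudinal_cohort`.
#' @return A [feature_table()].
#' @export
featurize_concatenated <- function(cohort) {
  out <- list(participant_id = cohort$ids)
  pv <- list()
  for (v in names(cohort$grids)) {
    m <- cohort$grids[[v]]
    for (j in seq_along(cohort$visit_years)) {
      yr <- cohort$visit_years[j]
      cn <- paste0(v, "__y", yr)
      out[[cn]] <- as.numeric(m[, j])
      pv[[cn]] <- tibble::tibble(column = cn, source_variable = v,
                                 statistic = paste0("visit_", yr),
                                 visit_year = yr)
    }
  }
  ft <- feature_table(tibble::as_tibble(out), dplyr::bind_rows(pv))
  append_fixed(ft, cohort)
}

#' Rebuild the longitudinal grid from a concatenated feature table
#'
#' Inverse of [featurize_concatenated()] via column provenance; used to
#' verify the reshape round-trips exactly.
#'
#' @param table A concatenated [feature_table()].
#' @param visit_years The cohort's visit schedule.
#' @return A `longitudinal_cohort` (no fixed covariates or truth).
#' @export
unconcatenate <- function(table, visit_years) {
  pv <- provenance(table)
  pv <- pv[!is.na(pv$visit_year), ]
  grids <- lapply(split(pv, pv$source_variable), function(sub) {
    sub <- sub[order(sub$visit_year), ]
    m <- as.matrix(table[sub$column])
    dimnames(m) <- list(table$participant_id, sub$visit_year)
    m
  })
  new_cohort_from_grids(grids[unique(pv$source_variable)], visit_years)
}

#' Run one featurization strategy by name
#'
#' Dispatch used by the benchmark harness. Data-dependent featurizer state
#' (pruning set, cluster models) is fitted on `train_ids` only and applied
#' to everyone, so test folds never influence it.
#'
#' @param cohort A complete `longitudinal_cohort`.
#' @param strategy One of `"ts_features"`, `"clusters"`, `"last_visit"`,
#'   `"concatenated"`, `"baseline"`.
#' @param train_ids Ids the featurizer state may depend on (default: all).
#' @param ts_features Optional precomputed [extract_ts_features()] table
#'   (extraction is per-participant pure, so it can be shared across folds).
#' @param rho_max Spearman pruning threshold for `"ts_features"`.
#' @param cluster_args List of arguments forwarded to
#'   [cluster_trajectories()] for `"clusters"`.
#' @return A [feature_table()] covering all cohort ids, with any fitted
#'   state in attributes (`"dropped"`, `"cluster_models"`).
#' @export
featurize_strategy <- function(cohort, strategy, train_ids = NULL,
                               ts_features = NULL, rho_max = 0.95,
                               cluster_args = list()) {
  train_ids <- train_ids %||% cohort$ids
  switch(strategy,
    ts_features = {
      ft <- ts_features %||% extract_ts_features(cohort)
      pruned_train <- prune_features(ft_rows(ft, train_ids), rho_max)
      out <- ft_select(ft, setdiff(names(pruned_train), "participant_id"))
      attr(out, "dropped") <- attr(pruned_train, "dropped")
      out
    },
    clusters = {
      models <- do.call(featurize_clusters,
                        c(list(cohort = cohort, ids = train_ids),
                          cluster_args)) |>
        attr("cluster_models")
      featurize_clusters(cohort, models = models)
    },
    last_visit = featurize_cross_sectional(cohort, "last"),
    concatenated = featurize_concatenated(cohort),
    baseline = featurize_cross_sectional(cohort, "first"),
    stop("unknown strategy: ", strategy, call. = FALSE))
}

#' @export
#' @rdname featurize_strategy
strategy_names <- function() {
  c("ts_features", "clusters", "last_visit", "concatenated", "baseline")
}
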