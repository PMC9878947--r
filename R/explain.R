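# Wrap a fitted model (or a plain function of a feature table) as a
# risk-scoring function; explainers are read-only with respect to the model.
as_risk_fn <- function(model, horizon) {
  if (is.function(model)) return(model)
  stopifnot(inherits(model, "trajsurv_model"))
  function(ft) risk_at(predict_survival(model, ft, horizon), horizon)
}

make_loss_fn <- function(metric, outcome, horizon, G) {
  if (is.function(metric)) return(metric)
  switch(metric,
    cindex = function(risk) {
      1 - truncated_cindex(risk, outcome, horizon, G)
    },
    auc = function(risk) {
      1 - time_dependent_auc(risk, outcome, horizon, G)
    },
    stop("unknown loss metric: ", metric, call. = FALSE))
}

#' Permutation variable importance
#'
#' For each feature, the increase in loss (default one minus the truncated
#' concordance at the horizon) when that column is permuted across
#' participants, averaged over `n_perm` permutations; scores are normalized
#' by the maximum so the top feature scores 1.
#'
#' @param model A `trajsurv_model` or a function `f(feature_table) -> risk`.
#' @param features A [feature_table()].
#' @param outcome Outcome tibble aligned by id.
#' @param metric `"cindex"`, `"auc"`, or a function `f(risk) -> loss`.
#' @param horizon Evaluation horizon (default: max follow-up).
#' @param n_perm Permutations per feature.
#' @param seed Integer seed.
#' @return A `trajsurv_importance` tibble (`feature`, `raw`, `importance`)
#'   with the baseline loss and permutation count in attributes.
#' @export
permutation_importance <- function(model, features, outcome,
                                   metric = "cindex", horizon = NULL,
                                   n_perm = 10, seed = 1L) {
  out <- align_outcome(features, outcome)
  horizon <- horizon %||% max(out$time_years)
  G <- censoring_km(out)
  loss_fn <- make_loss_fn(metric, out, horizon, G)
  risk_fn <- as_risk_fn(model, horizon)
  baseline <- loss_fn(risk_fn(features))
  if (is.na(baseline)) stop("loss undefined on these data", call. = FALSE)
  set.seed(stage_seed(seed, "explain"))
  cols <- setdiff(names(features), "participant_id")
  n <- nrow(features)
  raw <- vapply(cols, function(cn) {
    mean(vapply(seq_len(n_perm), function(p) {
      ft2 <- features
      ft2[[cn]] <- ft2[[cn]][sample.int(n)]
      loss_fn(risk_fn(ft2))
    }, 1)) - baseline
  }, 1)
  mx <- max(raw)
  norm <- if (mx > 0) pmax(raw, 0) / mx else rep(0, length(raw))
  structure(tibble::tibble(feature = cols, raw = raw, importance = norm),
            baseline_loss = baseline, n_perm = n_perm,
            class = c("trajsurv_importance", "tbl_df", "tbl", "data.frame"))
}

#' Sampling-based Shapley attribution of a risk prediction
#'
#' Permutation-sampling estimate of Shapley values for one participant's
#' predicted risk at a horizon: feature orderings are sampled, absent
#' features are imputed from a background row (rows are cycled
#' deterministically so each contributes equally often — a stratified
#' draw that removes the background-sampling variance), and each
#' feature's marginal contribution is averaged. The base value is the mean background
#' prediction; the efficiency axiom (contributions sum to prediction minus
#' base value) is enforced by spreading the residual equally
#' (`phi_adjusted`), with the pre-adjustment estimate retained in `phi`.
#'
#' @param model A `trajsurv_model` or risk function.
#' @param subject One-row [feature_table()] (or an id present in
#'   `background`).
#' @param background Background [feature_table()] (reference population;
#'   subsample it beforehand if large).
#' @param horizon Risk horizon.
#' @param n_samples Number of sampled orderings (>= 1).
#' @param seed Integer seed.
#' @return A `trajsurv_shapley` tibble (`feature`, `value`, `phi`,
#'   `phi_adjusted`) with `base_value`, `prediction`, `n_samples`
#'   attributes.
#' @export
shapley_sampling <- function(model, subject, background, horizon,
                             n_samples = 200, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (!nrow(background)) stop("background must be non-empty", call. = FALSE)
  if (is.character(subject)) subject <- ft_rows(background, subject)
  stopifnot(nrow(subject) == 1)
  risk_fn <- as_risk_fn(model, horizon)
  cols <- setdiff(names(background), "participant_id")
  d <- length(cols)
  base_value <- mean(risk_fn(background))
  pred <- risk_fn(feature_table(subject[c("participant_id", cols)],
                                provenance(background)))
  set.seed(stage_seed(seed, "explain"))
  xs <- as.numeric(subject[1, cols])
  bg <- ft_matrix(background)[, cols, drop = FALSE]
  # build all evaluation rows in one batch: per sample, walk one ordering
  rows <- matrix(NA_real_, n_samples * (d + 1), d,
                 dimnames = list(NULL, cols))
  perms <- matrix(0L, n_samples, d)
  for (s in seq_len(n_samples)) {
    perm <- sample.int(d)
    perms[s, ] <- perm
    # cycle background rows deterministically: each row is used equally
    # often, so the background-draw variance vanishes (for additive
    # effects the background mean is integrated exactly)
    cur <- bg[(s - 1) %% nrow(bg) + 1, ]
    rows[(s - 1) * (d + 1) + 1, ] <- cur
    for (k in seq_len(d)) {
      cur[perm[k]] <- xs[perm[k]]
      rows[(s - 1) * (d + 1) + 1 + k, ] <- cur
    }
  }
  ft_rows_tbl <- feature_table(
    dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("S%07d", seq_len(nrow(rows)))),
      tibble::as_tibble(rows)),
    provenance(background))
  fv <- risk_fn(ft_rows_tbl)
  phi <- numeric(d)
  for (s in seq_len(n_samples)) {
    off <- (s - 1) * (d + 1)
    delta <- diff(fv[off + seq_len(d + 1)])
    phi[perms[s, ]] <- phi[perms[s, ]] + delta
  }
  phi <- phi / n_samples
  resid <- (pred - base_value) - sum(phi)
  structure(
    tibble::tibble(feature = cols, value = xs, phi = phi,
                   phi_adjusted = phi + resid / d),
    base_value = base_value, prediction = pred, n_samples = n_samples,
    class = c("trajsurv_shapley", "tbl_df", "tbl", "data.frame"))
}

#' Partial dependence of survival on cluster membership
#'
#' For a model trained on trajectory-cluster memberships: sets every
#' participant's membership for one variable to cluster `c` (all other
#' features unchanged), predicts, and averages the survival curves — one
#' curve per cluster.
#'
#' @param model A `trajsurv_model` trained on cluster features.
#' @param features The cluster [feature_table()] used for prediction.
#' @param variable Source variable name (its column is
#'   `<variable>__cluster`).
#' @param k Number of clusters (default: max observed membership).
#' @param time_grid Curve evaluation times.
#' @return A `trajsurv_pdp` tibble (`cluster`, `time`, `survival`).
#' @export
partial_dependence_clusters <- function(model, features, variable,
                                        k = NULL, time_grid) {
  cn <- if (variable %in% names(features)) variable
        else paste0(variable, "__cluster")
  if (!cn %in% names(features)) {
    stop("no cluster column for variable: ", variable, call. = FALSE)
  }
  k <- k %||% max(features[[cn]])
  rows <- lapply(seq_len(k), function(cc) {
    ft2 <- features
    ft2[[cn]] <- rep(as.numeric(cc), nrow(ft2))
    curves <- predict_survival(model, ft2, time_grid)
    tibble::tibble(cluster = cc, time = curves$time_grid,
                   survival = colMeans(curves$probs))
  })
  structure(dplyr::bind_rows(rows),
            variable = variable,
            class = c("trajsurv_pdp", "tbl_df", "tbl", "data.frame"))
}

#' Configuration for temporal-window importance
#'
#' @param n_permutations Permutations per importance estimate (default
#'   100).
#' @param w Window localization parameter in (0, 1): the reported window
#'   must capture at least `1 - w` of the variable's overall importance
#'   (default 0.1).
#' @param metric Loss metric, as in [permutation_importance()].
#' @param threshold Normalized-importance floor below which no window is
#'   reported (default 0.05).
#' @param alpha Significance level of the within-window ordering test
#'   (Benjamini-Hochberg corrected across variables).
#' @param seed Integer seed.
#' @return A `time_config` list.
#' @export
time_config <- function(n_permutations = 100, w = 0.1, metric = "cindex",
                        threshold = 0.05, alpha = 0.05, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (w <= 0 || w >= 1) stop("w must be in (0, 1)", call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations), w = w,
                 metric = metric, threshold = threshold, alpha = alpha,
                 seed = as.integer(seed)),
            class = "time_config")
}

# mean loss increase over n permutations of jointly permuting `cols`
# across participants (rows travel together, series stay intact)
perm_loss_increase <- function(features, cols, loss_fn, risk_fn, baseline,
                               n_perm) {
  n <- nrow(features)
  mean(vapply(seq_len(n_perm), function(p) {
    pi <- sample.int(n)
    ft2 <- features
    for (cn in cols) ft2[[cn]] <- ft2[[cn]][pi]
    loss_fn(risk_fn(ft2))
  }, 1)) - baseline
}

#' Temporal-window importance for per-visit models
#'
#' Model-agnostic explanation for models consuming per-visit inputs
#' (concatenation-style feature tables, or any plug-in risk function over
#' them). For each variable it reports: (1) overall importance — the mean
#' loss increase when the variable's entire series is permuted across
#' participants (kept intact within participant); (2) the smallest
#' contiguous visit window whose permutation achieves at least `1 - w` of
#' the overall importance (searched by increasing width, then left index,
#' so ties resolve toward the earliest window); (3) whether temporal
#' ordering inside the window matters, by a permutation test of
#' within-participant shuffling (Benjamini-Hochberg corrected across
#' variables); and (4) per-visit cell importances for the heatmap.
#'
#' @param model A `trajsurv_model` or risk function over the feature table.
#' @param features A per-visit [feature_table()] (see
#'   [featurize_concatenated()]); provenance defines the variable/visit
#'   grouping. Variables without visit structure (fixed covariates) are
#'   treated as single-cell series.
#' @param outcome Outcome tibble.
#' @param config A [time_config()].
#' @param horizon Risk/loss horizon (default max follow-up).
#' @return A `trajsurv_time` object: per-variable tibble (`variable`,
#'   `raw`, `importance`, `window_start`, `window_end`,
#'   `ordering_matters`, `p_order`, `p_adj`) plus the cell matrix in
#'   attribute `"cells"`.
#' @export
time_importance <- function(model, features, outcome,
                            config = time_config(), horizon = NULL) {
  out <- align_outcome(features, outcome)
  horizon <- horizon %||% max(out$time_years)
  G <- censoring_km(out)
  loss_fn <- make_loss_fn(config$metric, out, horizon, G)
  risk_fn <- as_risk_fn(model, horizon)
  baseline <- loss_fn(risk_fn(features))
  pv <- provenance(features)
  groups <- split(pv, pv$source_variable)
  groups <- lapply(groups, function(g) g[order(g$visit_year), ])
  vars <- names(groups)
  n_visit <- max(vapply(groups, nrow, 1L))
  set.seed(stage_seed(config$seed, "explain"))
  np <- config$n_permutations
  n <- nrow(features)

  overall <- setNames(numeric(length(vars)), vars)
  cells <- matrix(NA_real_, length(vars), n_visit,
                  dimnames = list(vars,
                                  paste0("visit_", seq_len(n_visit))))
  for (v in vars) {
    cols <- groups[[v]]$column
    overall[v] <- perm_loss_increase(features, cols, loss_fn, risk_fn,
                                     baseline, np)
    for (j in seq_along(cols)) {
      cells[v, j] <- perm_loss_increase(features, cols[j], loss_fn,
                                        risk_fn, baseline, np)
    }
  }
  mx <- max(overall)
  norm <- if (mx > 0) pmax(overall, 0) / mx else overall * 0

  res <- list()
  p_order <- setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    cols <- groups[[v]]$column
    m <- length(cols)
    win <- c(NA_integer_, NA_integer_)
    if (norm[v] > config$threshold) {
      target <- (1 - config$w) * overall[v]
      found <- FALSE
      for (width in seq_len(m)) {
        if (found) break
        for (start in seq_len(m - width + 1)) {
          imp <- if (width == m) overall[v] else {
            perm_loss_increase(features, cols[start:(start + width - 1)],
                               loss_fn, risk_fn, baseline, np)
          }
          if (imp >= target) {
            win <- c(start, start + width - 1)
            found <- TRUE
            break
          }
        }
      }
      # within-participant temporal shuffling inside the window
      if (win[2] > win[1]) {
        wc <- cols[win[1]:win[2]]
        vals <- as.matrix(features[wc])
        incr <- vapply(seq_len(np), function(p) {
          ft2 <- features
          shuf <- t(apply(vals, 1, sample))
          for (j in seq_along(wc)) ft2[[wc[j]]] <- shuf[, j]
          loss_fn(risk_fn(ft2)) - baseline
        }, 1)
        p_order[v] <- (1 + sum(incr <= 0)) / (np + 1)
      }
    }
    res[[v]] <- tibble::tibble(
      variable = v, raw = unname(overall[v]),
      importance = unname(norm[v]),
      window_start = win[1], window_end = win[2])
  }
  tab <- dplyr::bind_rows(res)
  tab$p_order <- p_order[tab$variable]
  tab$p_adj <- p.adjust(tab$p_order, method = "BH")
  tab$ordering_matters <- !is.na(tab$p_adj) & tab$p_adj < config$alpha
  structure(tab, cells = cells, baseline_loss = baseline, config = config,
            class = c("trajsurv_time", "tbl_df", "tbl", "data.frame"))
}
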