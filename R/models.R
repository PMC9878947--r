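#' Specify a survival learner
#'
#' A uniform specification over the three built-in families: unpenalized
#' proportional hazards (`"coxph"`), L1-penalized proportional hazards
#' (`"lasso_cox"`, penalty chosen on a validation split), and a random
#' survival forest (`"survival_forest"` via log-rank splitting).
#'
#' @param family Model family.
#' @param num_trees,min_node_size,mtry Survival-forest hyperparameters
#'   (defaults 500 trees, node size 15, `mtry = sqrt(p)`).
#' @param lambda Optional fixed penalty for `"lasso_cox"`; if `NULL` the
#'   penalty is selected by held-out partial likelihood (see
#'   [fit_survival_model()]).
#' @param seed Integer seed (forest bootstrap, penalty-tuning folds).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("coxph", "lasso_cox", "survival_forest"),
                       num_trees = 500L, min_node_size = 15L, mtry = NULL,
                       lambda = NULL, seed = 1L) {
  family <- match.arg(family)
  if (num_trees < 1) stop("num_trees must be >= 1", call. = FALSE)
  structure(list(family = family, num_trees = as.integer(num_trees),
                 min_node_size = as.integer(min_node_size), mtry = mtry,
                 lambda = lambda, seed = as.integer(seed)),
            class = "model_spec")
}

align_outcome <- function(features, outcome) {
  idx <- match(features$participant_id, outcome$participant_id)
  if (anyNA(idx)) stop("outcome missing for some participants",
                       call. = FALSE)
  outcome[idx, ]
}

# Breslow cumulative baseline hazard on the training data
breslow_basehaz <- function(lp, time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; elp <- exp(lp[ord])
  # risk-set sums: subjects with time >= t
  rev_cum <- rev(cumsum(rev(elp)))
  ev_times <- unique(time[event == 1])
  dN <- vapply(ev_times, function(s) sum(event == 1 & time == s), 1)
  denom <- vapply(ev_times, function(s) rev_cum[match(TRUE, time >= s)], 1)
  list(time = ev_times, cumhaz = cumsum(dN / denom))
}

# Breslow partial log-likelihood of held-out data at given linear predictors
cox_partial_loglik <- function(lp, time, event) {
  if (!any(event == 1)) return(NA_real_)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; lp <- lp[ord]
  rev_cum <- rev(cumsum(rev(exp(lp))))
  risk_log <- vapply(which(event == 1),
                     function(i) log(rev_cum[match(TRUE, time >= time[i])]),
                     1)
  sum(lp[event == 1]) - sum(risk_log)
}

#' Fit a survival model on a feature table
#'
#' All families expose the same contract: fit on a feature table plus an
#' outcome table, predict survival curves with [predict_survival()]. For
#' `"lasso_cox"` the penalty is chosen by seeded event-stratified 5-fold
#' cross-validated partial-likelihood deviance on the training rows (or,
#' when `validation_ids` is supplied, by maximizing the partial likelihood
#' of that held-out split), then the model is refitted on all rows at the
#' chosen penalty. For
#' `"coxph"`, constant or linearly dependent columns are dropped with a
#' warning (documented fallback for rank deficiency); if no column
#' survives, the fit errors.
#'
#' @param features A [feature_table()].
#' @param outcome Tibble with `participant_id`, `time_years`, `event`
#'   (needs >= 2 events).
#' @param spec A [model_spec()].
#' @param validation_ids Optional participant ids used only for penalty
#'   selection.
#' @return A `trajsurv_model`.
#' @export
fit_survival_model <- function(features, outcome, spec = model_spec(),
                               validation_ids = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  out <- align_outcome(features, outcome)
  if (sum(out$event) < 2) stop("need >= 2 events to fit", call. = FALSE)
  X <- ft_matrix(features)
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  time <- out$time_years; event <- out$event
  fit_state <- NULL
  cols <- colnames(X)

  if (spec$family == "coxph") {
    keep <- apply(X, 2, function(z) length(unique(z)) > 1)
    if (!any(keep)) stop("all features constant: rank-deficient design",
                         call. = FALSE)
    if (!all(keep)) {
      warning("dropping constant columns: ",
              paste(cols[!keep], collapse = ", "), call. = FALSE)
    }
    Xk <- X[, keep, drop = FALSE]
    df <- data.frame(Xk, check.names = FALSE)
    fit <- survival::coxph(
      survival::Surv(time, event) ~ .,
      data = df, x = FALSE, model = FALSE, ties = "breslow")
    beta <- coef(fit)
    if (anyNA(beta)) {
      warning("dropping linearly dependent columns: ",
              paste(names(beta)[is.na(beta)], collapse = ", "),
              call. = FALSE)
      beta[is.na(beta)] <- 0
    }
    fit_state <- list(beta = beta, used = colnames(Xk))
  } else if (spec$family == "lasso_cox") {
    y <- survival::Surv(time, event)
    # glmnet requires >= 2 columns; pad single-feature designs with a
    # zero column whose coefficient is discarded
    padded <- ncol(X) < 2
    if (padded) X <- cbind(X, `..pad` = 0)
    if (is.null(spec$lambda)) {
      if (!is.null(validation_ids)) {
        # explicit validation split: maximize its partial likelihood
        vidx <- which(features$participant_id %in% validation_ids)
        tidx <- setdiff(seq_len(nrow(X)), vidx)
        path <- glmnet::glmnet(X[tidx, , drop = FALSE], y[tidx, ],
                               family = "cox", standardize = TRUE,
                               nlambda = 60, lambda.min.ratio = 0.02)
        lp_val <- predict(path, newx = X[vidx, , drop = FALSE])
        ll <- apply(lp_val, 2, cox_partial_loglik,
                    time = time[vidx], event = event[vidx])
        lambda <- path$lambda[which.max(ll)]
      } else {
        # default: seeded, event-stratified 5-fold CV deviance — a single
        # small validation split is too noisy at low event counts and can
        # select the null model
        set.seed(stage_seed(spec$seed, "model"))
        foldid <- integer(nrow(X))
        for (g in split(seq_len(nrow(X)), event)) {
          foldid[sample(g)] <- rep_len(1:5, length(g))
        }
        cvfit <- glmnet::cv.glmnet(X, y, family = "cox",
                                   foldid = foldid, standardize = TRUE,
                                   nlambda = 60, lambda.min.ratio = 0.02)
        lambda <- cvfit$lambda.min
      }
    } else {
      lambda <- spec$lambda
    }
    final <- glmnet::glmnet(X, y, family = "cox", standardize = TRUE,
                            lambda = lambda)
    beta <- as.numeric(final$beta)
    names(beta) <- rownames(final$beta)
    beta <- beta[cols]
    fit_state <- list(beta = beta, used = cols, lambda = lambda)
    if (padded) X <- X[, cols, drop = FALSE]
  } else { # survival_forest
    fit <- ranger::ranger(
      x = data.frame(X, check.names = FALSE),
      y = survival::Surv(time, event),
      num.trees = spec$num_trees, min.node.size = spec$min_node_size,
      mtry = spec$mtry, seed = spec$seed, num.threads = 1,
      verbose = FALSE)
    fit_state <- list(forest = fit, used = cols)
  }

  lp <- NULL
  baseline <- NULL
  if (spec$family %in% c("coxph", "lasso_cox")) {
    lp <- as.numeric(X[, fit_state$used, drop = FALSE] %*%
                       fit_state$beta[fit_state$used])
    baseline <- breslow_basehaz(lp, time, event)
  }
  structure(
    list(spec = spec, family = spec$family, columns = cols,
         provenance = provenance(features), state = fit_state,
         baseline = baseline,
         train_time_range = range(time)),
    class = "trajsurv_model")
}

#' @export
print.trajsurv_model <- function(x, ...) {
  cat("<trajsurv_model> family ", x$family, ", ",
      length(x$columns), " features\n", sep = "")
  invisible(x)
}

#' Predict survival curves
#'
#' Produces per-participant survival probabilities over a time grid
#' (years since the landmark). Proportional-hazards families use the
#' Breslow baseline cumulative hazard estimated on the training data;
#' forests use the per-tree Nelson-Aalen aggregation, step-interpolated
#' onto the grid. The returned curves satisfy `S(0) = 1`, lie in `[0, 1]`,
#' and are non-increasing in time.
#'
#' @param model A `trajsurv_model`.
#' @param features A [feature_table()] whose columns match the training
#'   provenance exactly.
#' @param time_grid Increasing evaluation times.
#' @return A `surv_curves` object (`ids`, `time_grid`, `probs` matrix).
#' @export
predict_survival <- function(model, features, time_grid) {
  miss <- setdiff(model$columns, setdiff(names(features), "participant_id"))
  extra <- setdiff(setdiff(names(features), "participant_id"),
                   model$columns)
  if (length(miss) || length(extra)) {
    stop("feature columns do not match training provenance; missing: [",
         paste(miss, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  X <- ft_matrix(features)[, model$columns, drop = FALSE]
  grid <- sort(unique(c(0, as.numeric(time_grid))))
  if (model$family %in% c("coxph", "lasso_cox")) {
    lp <- as.numeric(X[, model$state$used, drop = FALSE] %*%
                       model$state$beta[model$state$used])
    H0 <- stepfun_eval(model$baseline$time, model$baseline$cumhaz, grid)
    probs <- exp(-outer(exp(lp), H0))
  } else {
    pr <- predict(model$state$forest,
                  data = data.frame(X, check.names = FALSE),
                  num.threads = 1)
    st <- pr$unique.death.times
    sv <- pr$survival  # n x length(st)
    probs <- t(vapply(seq_len(nrow(sv)), function(i) {
      stepfun_eval(st, sv[i, ], grid, left = 1)
    }, numeric(length(grid))))
  }
  probs[, grid == 0] <- 1
  probs <- pmin(pmax(probs, 0), 1)
  # enforce monotone non-increasing rows against numerical drift
  probs <- t(apply(probs, 1, cummin))
  structure(list(ids = features$participant_id, time_grid = grid,
                 probs = probs),
            class = "surv_curves")
}

# right-continuous step evaluation: value at largest knot <= t (left of
# first knot: `left`)
stepfun_eval <- function(knots, values, t, left = 0) {
  idx <- findInterval(t, knots)
  out <- c(left, values)[idx + 1]
  out
}

#' @export
print.surv_curves <- function(x, ...) {
  cat("<surv_curves> ", length(x$ids), " participants x ",
      length(x$time_grid), " times (",
      min(x$time_grid), "-", max(x$time_grid), "y)\n", sep = "")
  invisible(x)
}

#' Tidy survival curves into long format
#'
#' @param x A `surv_curves`.
#' @param ... Unused.
#' @return Tibble with `participant_id`, `time`, `survival`.
#' @method tidy surv_curves
#' @export
tidy.surv_curves <- function(x, ...) {
  tibble::tibble(
    participant_id = rep(x$ids, times = length(x$time_grid)),
    time = rep(x$time_grid, each = length(x$ids)),
    survival = as.vector(x$probs))
}

#' Risk score at a horizon
#'
#' Risk is defined as `1 - S(horizon | x)`, read off the survival curves by
#' right-continuous step interpolation.
#'
#' @param curves A `surv_curves`.
#' @param horizon Evaluation time (years since landmark).
#' @return Named numeric vector of risks.
#' @export
risk_at <- function(curves, horizon) {
  j <- max(which(curves$time_grid <= horizon))
  setNames(1 - curves$probs[, j], curves$ids)
}

#' @method tidy trajsurv_model
#' @export
tidy.trajsurv_model <- function(x, ...) {
  if (x$family %in% c("coxph", "lasso_cox")) {
    tibble::tibble(term = x$state$used,
                   estimate = as.numeric(x$state$beta[x$state$used]))
  } else {
    tibble::tibble(term = x$columns, estimate = NA_real_)
  }
}

#' @method glance trajsurv_model
#' @export
glance.trajsurv_model <- function(x, ...) {
  tibble::tibble(family = x$family, n_features = length(x$columns),
                 lambda = x$state$lambda %||% NA_real_)
}
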