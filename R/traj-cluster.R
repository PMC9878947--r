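#' The 24 trajectory summary measures
#'
#' A fixed, documented catalog of per-series summary measures describing
#' level, spread, total and relative change, linear fit, first-difference
#' and second-difference behaviour, and early-vs-late contrasts. Measures
#' with zero denominators (relative changes on zero levels, coefficient of
#' variation at mean zero) take the sentinel value 0 so every series maps to
#' a complete 24-vector.
#'
#' @param series Complete numeric series (length >= 3).
#' @param times Visit years.
#' @return Named numeric vector of length 24.
#' @export
traj_summary_measures <- function(series, times) {
  x <- as.numeric(series); t <- as.numeric(times)
  stopifnot(length(x) == length(t), length(x) >= 3, !anyNA(x))
  p <- length(x)
  d <- diff(x); dt <- diff(t); rate <- d / dt
  dd <- diff(d)
  mid <- ceiling(p / 2)
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  tr <- linear_trend(x, t)
  ssx <- sum((x - mean(x))^2)
  rsq <- if (ssx == 0) 0 else {
    fit <- tr[1] + tr[2] * t
    1 - sum((x - fit)^2) / ssx
  }
  c(range = max(x) - min(x),
    mean_over_time = mean(x),
    sd = sd(x),
    cv = safe_div(100 * sd(x), mean(x)),
    total_change = x[p] - x[1],
    mean_change_per_year = (x[p] - x[1]) / (t[p] - t[1]),
    change_rel_first = safe_div(x[p] - x[1], x[1]),
    change_rel_mean = safe_div(x[p] - x[1], mean(x)),
    slope = if (is.na(tr[2])) 0 else tr[2],
    rsq = rsq,
    max_first_diff = max(d),
    min_first_diff = min(d),
    mean_abs_first_diff = mean(abs(d)),
    max_abs_first_diff = max(abs(d)),
    sd_first_diff = sd(d),
    mean_rate = mean(rate),
    sd_rate = sd(rate),
    max_abs_rate = max(abs(rate)),
    mean_second_diff = mean(dd),
    mean_abs_second_diff = mean(abs(dd)),
    max_abs_second_diff = max(abs(dd)),
    ratio_abs2_abs1 = safe_div(mean(abs(dd)), mean(abs(d))),
    early_change = x[mid] - x[1],
    late_change = x[p] - x[mid])
}

traj_measure_matrix <- function(cohort, variable, ids = NULL) {
  m <- cohort$grids[[variable]]
  if (is.null(m)) stop("unknown variable: ", variable, call. = FALSE)
  if (!is.null(ids)) m <- m[match(ids, rownames(m)), , drop = FALSE]
  out <- t(vapply(seq_len(nrow(m)),
                  function(i) traj_summary_measures(m[i, ],
                                                    cohort$visit_years),
                  numeric(24)))
  dimnames(out) <- list(rownames(m), traj_measure_names())
  out
}

traj_measure_names <- function() {
  names(traj_summary_measures(c(0, 1, 2), c(0, 1, 2)))
}

# Ratio-type measures (relative change, CV) have heavy tails when levels
# pass near zero; each measure is capped at its training 1%/99% quantiles
# before factor analysis and clustering so single outliers cannot dominate
# the distances. The caps are training-data state, stored on the model and
# re-applied at out-of-sample assignment.

#' Select non-redundant trajectory measures by factor analysis
#'
#' Standardizes the measure matrix, performs an eigen-decomposition of its
#' correlation matrix, retains factors with eigenvalue > 1 (Kaiser rule),
#' varimax-rotates the retained loadings when more than one factor survives,
#' and keeps, for each factor, the single measure with the largest absolute
#' loading (duplicates dropped). Zero-variance measures are removed first.
#'
#' @param measure_matrix Numeric id x measure matrix (>= 2 rows).
#' @return Integer vector of selected column indices (ascending), with the
#'   retained factor count in attribute `"n_factors"`.
#' @export
factor_select_measures <- function(measure_matrix) {
  stopifnot(nrow(measure_matrix) >= 2)
  keep <- which(apply(measure_matrix, 2, sd) > 0)
  if (length(keep) == 0) stop("all measures constant", call. = FALSE)
  if (length(keep) == 1) {
    return(structure(keep, n_factors = 1L))
  }
  z <- scale(measure_matrix[, keep, drop = FALSE])
  cm <- cor(z)
  eg <- eigen(cm, symmetric = TRUE)
  nf <- max(1L, sum(eg$values > 1))
  load <- eg$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(nf)], 0)), nf)
  if (nf > 1) load <- varimax(load)$loadings[, , drop = FALSE]
  sel <- unique(apply(abs(load), 2, which.max))
  structure(sort(keep[sel]), n_factors = nf)
}

criterion_wss <- function(X, fits, k_range) {
  # elbow: k where the decrease in within-cluster sum of squares flattens
  # most sharply (largest second difference of the WSS curve)
  ks <- c(max(1, min(k_range) - 1), k_range, max(k_range) + 1)
  ks <- sort(unique(ks))
  w <- vapply(as.character(ks), function(k) fits[[k]]$tot.withinss, 1)
  idx <- which(ks %in% k_range & ks > min(ks) & ks < max(ks))
  sec <- (w[idx - 1] - w[idx]) - (w[idx] - w[idx + 1])
  ks[idx][which.max(sec)]
}

criterion_silhouette <- function(X, fits, k_range) {
  dd <- stats::dist(X)
  s <- vapply(k_range, function(k) {
    cl <- fits[[as.character(k)]]$cluster
    mean(cluster::silhouette(cl, dd)[, "sil_width"])
  }, 1)
  k_range[which.max(s)]
}

criterion_ch <- function(X, fits, k_range) {
  n <- nrow(X)
  tss <- sum(scale(X, scale = FALSE)^2)
  ch <- vapply(k_range, function(k) {
    w <- fits[[as.character(k)]]$tot.withinss
    ((tss - w) / (k - 1)) / (w / (n - k))
  }, 1)
  k_range[which.max(ch)]
}

criterion_gap <- function(X, fits, k_range, B = 20) {
  km_or_distinct <- function(x, k) {
    key <- do.call(paste, as.data.frame(x))
    if (k >= length(unique(key))) {
      list(cluster = match(key, unique(key)))
    } else {
      kmeans(x, k, nstart = 5)
    }
  }
  gp <- cluster::clusGap(X, FUN = km_or_distinct,
                         K.max = min(max(k_range), nrow(unique(X))),
                         B = B, verbose = FALSE)
  k <- cluster::maxSE(gp$Tab[, "gap"], gp$Tab[, "SE.sim"],
                      method = "firstSEmax")
  max(k, min(k_range))
}

#' Choose the number of trajectory clusters by criterion vote
#'
#' Runs k-means over the candidate range and lets each criterion
#' (within-cluster sum of squares elbow, mean silhouette width,
#' Calinski-Harabasz index, gap statistic) vote for a k; the majority wins,
#' ties broken toward the smaller k. For large inputs the criteria are
#' evaluated on a seeded subsample (cap 1000 rows).
#'
#' @param X Numeric matrix of selected (standardized) measures.
#' @param k_range Candidate cluster counts, default `2:6`.
#' @param criteria Criterion names among
#'   `"wss"`, `"silhouette"`, `"ch"`, `"gap"`.
#' @param seed Integer seed (k-means restarts, gap references, subsample).
#' @param max_n Subsample cap for criterion evaluation.
#' @return The chosen k, with the per-criterion votes in attribute
#'   `"votes"`.
#' @export
select_cluster_count <- function(X, k_range = 2:6,
                                 criteria = c("wss", "silhouette", "ch",
                                              "gap"),
                                 seed = 1L, max_n = 1000L) {
  if (length(k_range) == 0) stop("empty k_range", call. = FALSE)
  if (length(criteria) < 2) stop("need >= 2 criteria", call. = FALSE)
  set.seed(stage_seed(seed, "cv"))
  if (nrow(X) > max_n) X <- X[sample.int(nrow(X), max_n), , drop = FALSE]
  n_distinct <- nrow(unique(X))
  # kmeans supports at most one center per distinct point
  k_range <- k_range[k_range <= n_distinct]
  if (length(k_range) == 0) k_range <- 2L
  if (n_distinct <= 2) {
    votes <- setNames(rep(min(k_range), length(criteria)), criteria)
    return(structure(min(k_range), votes = votes))
  }
  ks_all <- sort(unique(c(max(1, min(k_range) - 1), k_range,
                          max(k_range) + 1)))
  fits <- lapply(ks_all, function(k) {
    if (k == 1) {
      list(tot.withinss = sum(scale(X, scale = FALSE)^2),
           cluster = rep(1L, nrow(X)))
    } else if (k > n_distinct) {
      list(tot.withinss = 0, cluster = NULL)
    } else {
      kmeans(X, k, nstart = 10, iter.max = 50)
    }
  })
  names(fits) <- as.character(ks_all)
  votes <- vapply(criteria, function(cr) {
    switch(cr,
           wss = criterion_wss(X, fits, k_range),
           silhouette = criterion_silhouette(X, fits, k_range),
           ch = criterion_ch(X, fits, k_range),
           gap = criterion_gap(X, fits, k_range),
           stop("unknown criterion: ", cr, call. = FALSE))
  }, 1)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  structure(min(winners), votes = votes)
}

#' Cluster the trajectories of one longitudinal variable
#'
#' The three-step pipeline: compute the 24 summary measures per participant,
#' select non-redundant measures by factor analysis, choose k by criterion
#' vote, and run k-means (seeded, multiple restarts) on the standardized
#' selected measures. Cluster labels are relabeled canonically — ordered by
#' ascending within-cluster mean of the mean-over-time measure — so
#' memberships are reproducible across initializations.
#'
#' @param cohort A complete `longitudinal_cohort`.
#' @param variable Variable name.
#' @param ids Optional participant subset to fit on (training ids).
#' @param k Fixed cluster count; if `NULL`, chosen by vote.
#' @param k_range,criteria,seed Passed to [select_cluster_count()].
#' @return A `traj_cluster_model`: selected measures, standardization,
#'   centroids, memberships, criterion votes.
#' @export
cluster_trajectories <- function(cohort, variable, ids = NULL, k = NULL,
                                 k_range = 2:6,
                                 criteria = c("wss", "silhouette", "ch",
                                              "gap"),
                                 seed = 1L) {
  M_raw <- traj_measure_matrix(cohort, variable, ids)
  caps_lo <- apply(M_raw, 2, quantile, 0.01, names = FALSE)
  caps_hi <- apply(M_raw, 2, quantile, 0.99, names = FALSE)
  M <- pmin(pmax(M_raw, rep(caps_lo, each = nrow(M_raw))),
            rep(caps_hi, each = nrow(M_raw)))
  dimnames(M) <- dimnames(M_raw)
  sel <- tryCatch(factor_select_measures(M),
                  error = function(e) structure(1L, n_factors = 1L))
  Ms <- M[, sel, drop = FALSE]
  ctr <- colMeans(Ms)
  scl <- apply(Ms, 2, sd); scl[scl == 0] <- 1
  X <- scale(Ms, center = ctr, scale = scl)
  votes <- NULL
  if (is.null(k)) {
    k <- select_cluster_count(X, k_range, criteria, seed)
    votes <- attr(k, "votes")
    k <- as.integer(k)
  }
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    warning("variable '", variable, "': only ", n_distinct,
            " distinct trajectories; reducing k", call. = FALSE)
    k <- max(n_distinct, 1L)
  }
  set.seed(stage_seed(seed, "model"))
  if (k == 1 || n_distinct == 1) {
    cl <- rep(1L, nrow(X))
    centroids <- matrix(colMeans(X), 1, ncol(X),
                        dimnames = list(NULL, colnames(X)))
  } else {
    km <- kmeans(X, k, nstart = 10, iter.max = 50)
    # canonical relabeling: order clusters by mean level, ascending
    lev <- tapply(M[, "mean_over_time"], km$cluster, mean)
    ord <- order(lev)
    relab <- match(seq_len(k), ord)
    cl <- relab[km$cluster]
    centroids <- km$centers[ord, , drop = FALSE]
    rownames(centroids) <- NULL
  }
  structure(
    list(variable = variable,
         selected_measures = colnames(M)[sel],
         selected_idx = as.integer(sel), n_factors = attr(sel, "n_factors"),
         caps_lo = caps_lo[sel], caps_hi = caps_hi[sel],
         center = ctr, scale = scl, k = as.integer(k),
         centroids = centroids, votes = votes,
         memberships = tibble::tibble(participant_id = rownames(M),
                                      cluster = as.integer(cl))),
    class = "traj_cluster_model")
}

#' @export
print.traj_cluster_model <- function(x, ...) {
  cat("<traj_cluster_model> '", x$variable, "': k = ", x$k,
      ", measures: ", paste(x$selected_measures, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assign participants to fitted trajectory clusters
#'
#' Out-of-sample assignment: each participant's selected measures are
#' standardized with the training centering/scaling and mapped to the
#' nearest centroid.
#'
#' @param model A `traj_cluster_model`.
#' @param cohort A `longitudinal_cohort`.
#' @param ids Optional participant subset.
#' @return Integer cluster memberships named by participant id.
#' @export
predict_clusters <- function(model, cohort, ids = NULL) {
  M <- traj_measure_matrix(cohort, model$variable, ids)
  Ms <- M[, model$selected_idx, drop = FALSE]
  Ms <- pmin(pmax(Ms, rep(model$caps_lo, each = nrow(Ms))),
             rep(model$caps_hi, each = nrow(Ms)))
  X <- scale(Ms, center = model$center, scale = model$scale)
  d2 <- outer(rowSums(X^2), rowSums(model$centroids^2), "+") -
    2 * X %*% t(model$centroids)
  cl <- max.col(-d2, ties.method = "first")
  setNames(as.integer(cl), rownames(M))
}

#' Trajectory-clustering featurization (strategy 2)
#'
#' One column per longitudinal variable holding the participant's cluster
#' membership (an integer in `1..k`), plus fixed covariates. When `models`
#' are supplied (fitted on training ids), memberships for the requested ids
#' come from nearest-centroid assignment; otherwise models are fitted on the
#' full cohort.
#'
#' @param cohort A complete `longitudinal_cohort`.
#' @param models Optional named list of `traj_cluster_model`s.
#' @param ids Optional participant subset for the output table.
#' @param ... Passed to [cluster_trajectories()] when fitting.
#' @return A [feature_table()] with the fitted models in attribute
#'   `"cluster_models"`.
#' @export
featurize_clusters <- function(cohort, models = NULL, ids = NULL, ...) {
  vars <- names(cohort$grids)
  if (is.null(models)) {
    models <- lapply(vars, function(v)
      cluster_trajectories(cohort, v, ids = ids, ...))
    names(models) <- vars
  }
  use_ids <- ids %||% cohort$ids
  out <- list(participant_id = use_ids)
  pv <- list()
  for (v in vars) {
    cn <- paste0(v, "__cluster")
    out[[cn]] <- as.numeric(predict_clusters(models[[v]], cohort, use_ids))
    pv[[cn]] <- tibble::tibble(column = cn, source_variable = v,
                               statistic = "cluster",
                               visit_year = NA_real_)
  }
  ft <- feature_table(tibble::as_tibble(out), dplyr::bind_rows(pv))
  ft <- append_fixed(ft, cohort)
  if (!is.null(ids)) ft <- ft_rows(ft, use_ids)
  attr(ft, "cluster_models") <- models
  ft
}
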