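#' Catalog of time-series summary statistics
#'
#' The fixed, documented catalog used by the massive-feature-extraction
#' strategy: each entry is a pure function of a complete numeric series and
#' its visit times returning one number. The catalog covers the classical
#' location/spread statistics, the endpoints, the linear trend (regression
#' on visit years), and the "lesser-known" series statistics: absolute
#' energy, c3 nonlinearity, time-reversal asymmetry, autocorrelation at lags
#' 1 and 2, a sample-entropy variant, mean absolute change,
#' change-in-quantiles, counts above/below the mean and the longest strip
#' above the mean. Statistics that are undefined on a series (e.g. zero
#' variance for autocorrelation, no template matches for entropy) return
#' `NA`, which the downstream NA-pruning rule removes.
#'
#' @return Named list of functions `f(x, t)`.
#' @export
ts_stat_catalog <- function() {
  list(
    minimum       = function(x, t) min(x),
    maximum       = function(x, t) max(x),
    mean          = function(x, t) mean(x),
    median        = function(x, t) median(x),
    variance      = function(x, t) var(x),
    std_dev       = function(x, t) sd(x),
    first_value   = function(x, t) x[1],
    last_value    = function(x, t) x[length(x)],
    linear_intercept = function(x, t) linear_trend(x, t)[1],
    linear_slope  = function(x, t) linear_trend(x, t)[2],
    abs_energy    = function(x, t) sum(x^2),
    mean_abs_change = function(x, t) mean(abs(diff(x))),
    c3_lag1       = function(x, t) ts_c3(x, 1L),
    time_rev_asym_lag1 = function(x, t) ts_time_reversal(x, 1L),
    autocorr_lag1 = function(x, t) ts_autocorrelation(x, 1L),
    autocorr_lag2 = function(x, t) ts_autocorrelation(x, 2L),
    sample_entropy = function(x, t) ts_sample_entropy(x),
    change_quantiles_25_75 = function(x, t) ts_change_quantiles(x, 0.25, 0.75),
    count_above_mean = function(x, t) sum(x > mean(x)),
    count_below_mean = function(x, t) sum(x < mean(x)),
    longest_strike_above_mean = function(x, t) ts_longest_strike(x > mean(x))
  )
}

linear_trend <- function(x, t) {
  vt <- mean((t - mean(t))^2)
  if (vt == 0) return(c(mean(x), NA_real_))
  b <- mean((t - mean(t)) * (x - mean(x))) / vt
  c(mean(x) - b * mean(t), b)
}

ts_c3 <- function(x, lag = 1L) {
  n <- length(x)
  if (n < 2 * lag + 1) return(NA_real_)
  i <- seq_len(n - 2 * lag)
  mean(x[i + 2 * lag] * x[i + lag] * x[i])
}

ts_time_reversal <- function(x, lag = 1L) {
  n <- length(x)
  if (n < 2 * lag + 1) return(NA_real_)
  i <- seq_len(n - 2 * lag)
  mean(x[i + 2 * lag]^2 * x[i + lag] - x[i + lag] * x[i]^2)
}

ts_autocorrelation <- function(x, lag = 1L) {
  n <- length(x)
  if (n <= lag) return(NA_real_)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v == 0) return(NA_real_)
  sum((x[seq_len(n - lag)] - mu) * (x[seq_len(n - lag) + lag] - mu)) /
    ((n - lag) * v)
}

# Sample entropy (m = 2, tolerance r = 0.2 * sd); NA when no template pairs
# match at either length (short low-variance series), by design pruned later.
ts_sample_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < m + 2 || is.na(r) || r == 0) return(NA_real_)
  count_matches <- function(mm) {
    tmpl <- stats::embed(x, mm)[, mm:1, drop = FALSE]
    k <- nrow(tmpl)
    cnt <- 0L
    for (i in seq_len(k - 1)) {
      d <- abs(tmpl[(i + 1):k, , drop = FALSE] -
                 matrix(tmpl[i, ], k - i, mm, byrow = TRUE))
      cnt <- cnt + sum(apply(d, 1, max) <= r)
    }
    cnt
  }
  b <- count_matches(m)
  a <- count_matches(m + 1L)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

ts_change_quantiles <- function(x, q_lo, q_hi) {
  qs <- quantile(x, c(q_lo, q_hi), names = FALSE, type = 7)
  inside <- x >= qs[1] & x <= qs[2]
  both <- inside[-length(x)] & inside[-1]
  if (!any(both)) return(0)
  mean(abs(diff(x))[both])
}

ts_longest_strike <- function(b) {
  if (!any(b)) return(0)
  r <- rle(b)
  max(r$lengths[r$values])
}

#' Evaluate one time-series statistic on a series
#'
#' @param series Complete numeric series (no missing values).
#' @param times Visit years, same length as `series`.
#' @param stat A statistic name from [ts_stat_catalog()] or a function
#'   `f(x, t)`.
#' @return A single number; `NA` when the statistic is undefined on the
#'   series (handled downstream by the NA-pruning rule).
#' @export
compute_ts_statistic <- function(series, times, stat) {
  stopifnot(length(series) == length(times), !anyNA(series))
  f <- if (is.function(stat)) stat else ts_stat_catalog()[[stat]]
  if (is.null(f)) stop("unknown statistic: ", stat, call. = FALSE)
  as.numeric(f(series, times))
}

#' Massive time-series feature extraction (strategy 1)
#'
#' Evaluates every catalog statistic on every longitudinal variable of
#' every participant, producing one `variable__statistic` column per pair,
#' and appends the fixed covariates as pass-through columns. Extraction is
#' a pure per-participant map, so it can be computed once for a cohort and
#' pruned per training split.
#'
#' @param cohort A complete `longitudinal_cohort`.
#' @param catalog Named list of statistics (default [ts_stat_catalog()]).
#' @return A [feature_table()].
#' @export
extract_ts_features <- function(cohort, catalog = ts_stat_catalog()) {
  if (length(catalog) == 0) stop("catalog must be non-empty", call. = FALSE)
  tt <- cohort$visit_years
  out <- list(participant_id = cohort$ids)
  pv <- list()
  for (v in names(cohort$grids)) {
    m <- cohort$grids[[v]]
    for (s in names(catalog)) {
      f <- catalog[[s]]
      cn <- paste0(v, "__", s)
      out[[cn]] <- if (nrow(m)) {
        vapply(seq_len(nrow(m)), function(i) as.numeric(f(m[i, ], tt)), 1)
      } else numeric(0)
      pv[[cn]] <- tibble::tibble(column = cn, source_variable = v,
                                 statistic = s, visit_year = NA_real_)
    }
  }
  ft <- feature_table(tibble::as_tibble(out), dplyr::bind_rows(pv))
  append_fixed(ft, cohort)
}

#' Prune a feature table (NA, constant, and correlated columns)
#'
#' Applies, in order: (1) drop trajectory columns containing any missing
#' value; (2) drop columns with a single unique value; (3) order the
#' remaining trajectory columns lexicographically by
#' (source variable, statistic) and, for every pair with absolute Spearman
#' correlation at or above `rho_max`, drop the later column. Fixed
#' (demographic) pass-through columns are always kept and never enter the
#' correlation sweep. The operation is idempotent.
#'
#' @param table A [feature_table()].
#' @param rho_max Spearman correlation threshold (default 0.95).
#' @return The pruned [feature_table()]; dropped columns and reasons are in
#'   attribute `"dropped"`.
#' @export
prune_features <- function(table, rho_max = 0.95) {
  pv <- provenance(table)
  fixed_cols <- pv$column[pv$statistic == "fixed"]
  traj <- setdiff(pv$column, fixed_cols)
  ordkey <- pv[match(traj, pv$column), ]
  traj <- traj[order(ordkey$source_variable, ordkey$statistic,
                     ordkey$visit_year, method = "radix")]
  dropped <- list()
  m <- ft_matrix(table)[, traj, drop = FALSE]
  has_na <- colSums(is.na(m)) > 0
  if (any(has_na)) {
    dropped$missing <- traj[has_na]
    traj <- traj[!has_na]; m <- m[, traj, drop = FALSE]
  }
  n_uniq <- apply(m, 2, function(col) length(unique(col)))
  if (any(n_uniq <= 1)) {
    dropped$constant <- traj[n_uniq <= 1]
    traj <- traj[n_uniq > 1]; m <- m[, traj, drop = FALSE]
  }
  if (length(traj) > 1 && nrow(m) > 1) {
    rk <- apply(m, 2, rank)
    cm <- abs(suppressWarnings(cor(rk)))
    keep <- rep(TRUE, length(traj))
    for (j in seq_along(traj)[-1]) {
      if (any(cm[which(keep[seq_len(j - 1)]), j] >= rho_max)) {
        keep[j] <- FALSE
      }
    }
    dropped$correlated <- traj[!keep]
    traj <- traj[keep]
  }
  out <- ft_select(table, c(traj, fixed_cols))
  attr(out, "dropped") <- dropped
  out
}
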