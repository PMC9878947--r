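#' Kaplan-Meier estimate of the censoring distribution
#'
#' Estimates `G(t) = P(censoring time > t)` by Kaplan-Meier with the roles
#' of events and censorings reversed. `G` feeds the inverse probability of
#' censoring weights (IPCW) used by all censoring-adjusted metrics: a
#' subject observed to fail at `t <= horizon` is weighted by `1/G(t-)`, a
#' subject event-free through the horizon by `1/G(horizon-)`.
#'
#' @param outcome Tibble with `time_years` and `event`.
#' @return A `censoring_km` object with step knots and values.
#' @export
censoring_km <- function(outcome) {
  stopifnot(nrow(outcome) >= 1)
  sf <- survival::survfit(
    survival::Surv(outcome$time_years, 1 - outcome$event) ~ 1)
  structure(list(time = sf$time, surv = sf$surv), class = "censoring_km")
}

# G(t), right-continuous
G_at <- function(G, t) stepfun_eval(G$time, G$surv, t, left = 1)

# G(t-): value just before t
G_minus <- function(G, t) {
  vapply(t, function(s) {
    idx <- which(G$time < s)
    if (length(idx) == 0) 1 else G$surv[max(idx)]
  }, 1)
}

# Cases fail by the horizon; controls are known event-free through it —
# including subjects administratively censored exactly at the horizon,
# whose control weight uses G(horizon-) (identical to G(horizon) whenever
# the censoring distribution has no mass exactly there).
ipcw_parts <- function(risk, outcome, horizon, G) {
  time <- outcome$time_years; event <- outcome$event
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon | (time == horizon & event == 0)
  g_case <- G_minus(G, time[is_case])
  g_ctrl <- G_minus(G, horizon)
  if ((any(is_case) && any(g_case <= 0)) || (any(is_ctrl) && g_ctrl <= 0)) {
    warning("censoring survival reaches 0 before the horizon; ",
            "metric undefined there (truncate the evaluation horizon)",
            call. = FALSE)
    return(NULL)
  }
  list(case_risk = risk[is_case], ctrl_risk = risk[is_ctrl],
       w_case = 1 / g_case,
       w_ctrl = rep(1 / g_ctrl, sum(is_ctrl)))
}

#' IPCW time-dependent (cumulative/dynamic) AUC
#'
#' The weighted probability that a case (event by the horizon) is ranked
#' above a control (event-free through the horizon), ties counted one half;
#' case weights `1/G(t-)`, control weights `1/G(horizon-)`. With no
#' censoring this reduces to the plain binary AUC of event-by-horizon
#' status.
#'
#' @param risk Per-participant risk scores (higher = earlier event).
#' @param outcome Tibble with `time_years`, `event`, aligned with `risk`.
#' @param horizon Evaluation time.
#' @param G Optional precomputed [censoring_km()].
#' @return AUC in `[0, 1]`, or `NA` when there are no cases or no controls
#'   at the horizon (sentinel, excluded from aggregation).
#' @export
time_dependent_auc <- function(risk, outcome, horizon, G = NULL) {
  stopifnot(length(risk) == nrow(outcome), all(is.finite(risk)))
  G <- G %||% censoring_km(outcome)
  parts <- ipcw_parts(risk, outcome, horizon, G)
  if (is.null(parts)) return(NA_real_)
  if (!length(parts$case_risk) || !length(parts$ctrl_risk)) {
    return(NA_real_)
  }
  cmp <- outer(parts$case_risk, parts$ctrl_risk,
               function(a, b) (a > b) + 0.5 * (a == b))
  w <- outer(parts$w_case, parts$w_ctrl)
  sum(w * cmp) / sum(w)
}

#' IPCW truncated concordance index
#'
#' Censoring-adjusted concordance over pairs whose earlier observed time is
#' an event before `tau`: pair (i, j) with `T_i < T_j`, `event_i = 1`,
#' `T_i < tau` gets weight `1/G(T_i-)^2`; concordant when `risk_i >
#' risk_j`, ties one half. With no censoring this reduces to Harrell's C
#' restricted to `tau`. (Harrell's unweighted version is deliberately not
#' used as the headline metric: it ignores the censoring distribution.)
#'
#' @param risk Per-participant risk scores.
#' @param outcome Tibble with `time_years`, `event`.
#' @param tau Truncation horizon (defaults to max follow-up).
#' @param G Optional precomputed [censoring_km()].
#' @return Concordance in `[0, 1]`, or `NA` with no comparable pairs.
#' @export
truncated_cindex <- function(risk, outcome, tau = NULL, G = NULL) {
  stopifnot(length(risk) == nrow(outcome))
  time <- outcome$time_years; event <- outcome$event
  tau <- tau %||% max(time)
  G <- G %||% censoring_km(outcome)
  ev <- which(event == 1 & time < tau)
  if (!length(ev)) return(NA_real_)
  g <- G_minus(G, time[ev])
  if (any(g <= 0)) {
    warning("censoring survival reaches 0 before tau; pairs undefined",
            call. = FALSE)
    return(NA_real_)
  }
  num <- 0; den <- 0
  for (k in seq_along(ev)) {
    i <- ev[k]
    later <- time > time[i]
    m <- sum(later)
    if (!m) next
    w <- 1 / g[k]^2
    conc <- sum(risk[later] < risk[i]) + 0.5 * sum(risk[later] == risk[i])
    num <- num + w * conc
    den <- den + w * m
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' IPCW Brier score and integrated Brier score
#'
#' `brier_score()` is the censoring-weighted mean squared difference
#' between predicted survival and observed event-free status at the
#' horizon: failures by the horizon contribute `S(h|x)^2 / G(T-)`,
#' survivors `(1 - S(h|x))^2 / G(h-)`, subjects censored before the horizon
#' contribute nothing. `integrated_brier()` is the time-average over a grid
#' by the trapezoid rule.
#'
#' @param curves A `surv_curves` from [predict_survival()].
#' @param outcome Tibble aligned with the curves' ids.
#' @param horizon Evaluation time (must be covered by the curve grid).
#' @param G Optional precomputed [censoring_km()].
#' @return A number in `[0, 1]`.
#' @export
brier_score <- function(curves, outcome, horizon, G = NULL) {
  out <- outcome[match(curves$ids, outcome$participant_id), ]
  G <- G %||% censoring_km(out)
  S <- 1 - risk_at(curves, horizon)
  time <- out$time_years; event <- out$event
  fail <- time <= horizon & event == 1
  alive <- time > horizon | (time == horizon & event == 0)
  g_fail <- G_minus(G, time[fail])
  g_h <- G_minus(G, horizon)
  if ((any(fail) && any(g_fail <= 0)) || (any(alive) && g_h <= 0)) {
    warning("censoring survival reaches 0 before the horizon", call. = FALSE)
    return(NA_real_)
  }
  contrib <- numeric(length(time))
  contrib[fail] <- S[fail]^2 / g_fail
  contrib[alive] <- (1 - S[alive])^2 / g_h
  mean(contrib)
}

#' @rdname brier_score
#' @param grid Increasing times for the integrated version.
#' @export
integrated_brier <- function(curves, outcome, grid, G = NULL) {
  out <- outcome[match(curves$ids, outcome$participant_id), ]
  G <- G %||% censoring_km(out)
  bs <- vapply(grid, function(h) brier_score(curves, out, h, G), 1)
  ok <- !is.na(bs)
  if (sum(ok) < 2) return(NA_real_)
  g <- grid[ok]; b <- bs[ok]
  sum(diff(g) * (head(b, -1) + tail(b, -1)) / 2) / (max(g) - min(g))
}

#' Event-density weights over a time grid
#'
#' Kaplan-Meier mass of the event-time distribution falling in each grid
#' interval `(t_{k-1}, t_k]` (with `t_0 = 0`), used to weight time-dependent
#' AUCs into the integrated AUC.
#'
#' @param outcome Tibble with `time_years`, `event`.
#' @param grid Increasing evaluation times.
#' @return Non-negative weights, one per grid point (not normalized).
#' @export
event_density_weights <- function(outcome, grid) {
  sf <- survival::survfit(
    survival::Surv(outcome$time_years, outcome$event) ~ 1)
  S_at <- function(t) stepfun_eval(sf$time, sf$surv, t, left = 1)
  edges <- c(0, grid)
  S_edges <- S_at(edges)
  pmax(-diff(S_edges), 0)
}

#' Integrated (density-weighted) AUC
#'
#' Weighted mean of time-dependent AUCs over the grid, weights proportional
#' to the Kaplan-Meier-estimated event-density mass of each grid interval
#' and renormalized over the grid points where the AUC is defined.
#'
#' @param aucs Time-dependent AUCs over `grid` (may contain `NA`).
#' @param grid The evaluation grid.
#' @param outcome Outcome table used for the density weights (ignored when
#'   `weights` is given).
#' @param weights Optional explicit non-negative weights.
#' @return The weighted mean, or `NA` if no AUC is defined or no weight
#'   mass lies on defined points.
#' @export
integrated_auc <- function(aucs, grid, outcome = NULL, weights = NULL) {
  stopifnot(length(aucs) == length(grid))
  if (is.null(weights)) {
    stopifnot(!is.null(outcome))
    weights <- event_density_weights(outcome, grid)
  }
  ok <- !is.na(aucs) & weights > 0
  if (!any(ok)) return(NA_real_)
  sum(aucs[ok] * weights[ok]) / sum(weights[ok])
}

#' Censoring-adjusted classification metrics at the F1-optimal cutoff
#'
#' Sweeps binary cutoffs over the unique risk values; at each cutoff the
#' IPCW-weighted confusion matrix for event-by-horizon status is computed
#' (cases weighted `1/G(T-)`, horizon survivors `1/G(horizon)`, earlier
#' censorings excluded), and the cutoff maximizing F1 is returned (ties
#' broken toward the lower cutoff) together with sensitivity, specificity,
#' PPV, NPV, F1 and Matthews correlation at that cutoff.
#'
#' @param risk Per-participant risk scores.
#' @param outcome Tibble with `time_years`, `event`.
#' @param horizon Evaluation time.
#' @param G Optional precomputed [censoring_km()].
#' @return One-row tibble (`cutoff`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `f1`, `mcc`); all-`NA` sentinels when one class is absent.
#' @export
classification_at_horizon <- function(risk, outcome, horizon, G = NULL) {
  G <- G %||% censoring_km(outcome)
  parts <- ipcw_parts(risk, outcome, horizon, G)
  sentinel <- tibble::tibble(cutoff = NA_real_, sensitivity = NA_real_,
                             specificity = NA_real_, ppv = NA_real_,
                             npv = NA_real_, f1 = NA_real_, mcc = NA_real_)
  if (is.null(parts)) return(sentinel)
  if (!length(parts$case_risk) || !length(parts$ctrl_risk)) return(sentinel)
  P <- sum(parts$w_case); N <- sum(parts$w_ctrl)
  cutoffs <- sort(unique(c(parts$case_risk, parts$ctrl_risk)))
  best <- NULL
  for (ct in cutoffs) {
    tp <- sum(parts$w_case[parts$case_risk >= ct])
    fp <- sum(parts$w_ctrl[parts$ctrl_risk >= ct])
    fn <- P - tp; tn <- N - fp
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (is.null(best) || f1 > best$f1 + 1e-12) {
      best <- list(cutoff = ct, tp = tp, fp = fp, fn = fn, tn = tn, f1 = f1)
    }
  }
  den <- sqrt((best$tp + best$fp) * (best$tp + best$fn) *
                (best$tn + best$fp) * (best$tn + best$fn))
  mcc <- if (den == 0) 0 else
    (best$tp * best$tn - best$fp * best$fn) / den
  tibble::tibble(
    cutoff = best$cutoff,
    sensitivity = best$tp / P,
    specificity = best$tn / N,
    ppv = if (best$tp + best$fp == 0) NA_real_ else
      best$tp / (best$tp + best$fp),
    npv = if (best$tn + best$fn == 0) NA_real_ else
      best$tn / (best$tn + best$fn),
    f1 = best$f1, mcc = mcc)
}
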