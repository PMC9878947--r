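# Per-stage seeds derived from the global seed so that each simulation stage
# is independently reproducible; kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offset <- c(trajectories = 11L, missing = 23L, outcome = 37L,
              cv = 53L, model = 71L, explain = 89L, boot = 97L)[[stage]]
  as.integer((as.numeric(seed) %% 20000) * 100000 + offset * 101)
}

#' Simulate latent-class longitudinal trajectories
#'
#' Draws, for each participant and longitudinal variable, a latent
#' trajectory class from the variable's class probabilities, then evaluates
#' the class profile (with per-person random intercept/slope deviations for
#' continuous and ordinal variables) at the visit schedule and adds
#' measurement noise. Binary variables follow their class state sequence,
#' switching at the profile's switch year. Latent truth (class labels,
#' per-person latent intercept/slope/mean level) is attached for downstream
#' outcome simulation and recovery tests.
#'
#' @param config A [cohort_config()].
#' @return A `longitudinal_cohort` with truth attached.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(stage_seed(config$seed, "trajectories"))
  n <- config$n_participants
  tt <- config$visit_years
  p <- length(tt)
  ids <- sprintf("P%05d", seq_len(max(n, 0)))
  if (n == 0) ids <- character(0)

  fixed <- tibble::tibble(participant_id = ids)
  for (nm in names(config$fixed_covariates)) {
    gen <- config$fixed_covariates[[nm]]
    fixed[[nm]] <- switch(gen[[1]],
      normal = rnorm(n, gen[[2]], gen[[3]]),
      bernoulli = rbinom(n, 1, gen[[2]]),
      stop("unknown fixed covariate generator: ", gen[[1]], call. = FALSE))
  }

  grids <- list()
  truth_rows <- list()
  for (vs in config$variables) {
    k <- length(vs$class_profiles)
    cls <- if (n > 0) sample.int(k, n, replace = TRUE, prob = vs$class_probs)
           else integer(0)
    if (vs$kind == "binary") {
      pat <- vapply(vs$class_profiles, function(pr) {
        sw <- pr$switch_time
        if (is.na(sw)) rep(pr$state0, p)
        else ifelse(tt < sw, pr$state0, pr$state1)
      }, numeric(p))                     # p x k
      m <- t(pat)[cls, , drop = FALSE]   # n x p
      intercept <- rep(NA_real_, n); slope <- rep(NA_real_, n)
      mean_level <- if (n > 0) rowMeans(m) else numeric(0)
    } else {
      a0 <- vapply(vs$class_profiles, function(pr) pr$intercept, 1)[cls]
      b0 <- vapply(vs$class_profiles, function(pr) pr$slope, 1)[cls]
      cv <- vapply(vs$class_profiles,
                   function(pr) pr$curvature %||% 0, 1)[cls]
      intercept <- a0 + rnorm(n) * vs$ranef_intercept_sd
      slope <- b0 + rnorm(n) * vs$ranef_slope_sd
      latent <- outer(intercept, rep(1, p)) + outer(slope, tt) +
        outer(cv, tt^2)
      m <- latent + matrix(rnorm(n * p), n, p) * vs$noise_sd
      if (vs$kind == "ordinal") {
        m <- pmin(pmax(round(m), 1), vs$levels)
        latent_cl <- pmin(pmax(latent, 1), vs$levels)
        mean_level <- if (n > 0) rowMeans(latent_cl) else numeric(0)
      } else {
        mean_level <- intercept + slope * mean(tt) +
          (if (any(cv != 0)) cv * mean(tt^2) else 0)
      }
    }
    dimnames(m) <- list(ids, tt)
    grids[[vs$name]] <- m
    truth_rows[[vs$name]] <- tibble::tibble(
      participant_id = ids, variable = vs$name, class = cls,
      intercept = intercept, slope = slope, mean_level = mean_level)
  }
  truth <- dplyr::bind_rows(truth_rows)
  new_cohort_from_grids(grids, tt, fixed = fixed, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True per-participant log-hazard linear predictor
#'
#' Evaluates the configured hazard terms against the cohort's latent truth
#' (classes, latent slopes and mean levels) and fixed covariates.
#'
#' @param cohort A simulated cohort with truth attached.
#' @param config The [cohort_config()] used to simulate it.
#' @return Numeric vector of log-hazard contributions, aligned with
#'   `cohort$ids`.
#' @export
true_linear_predictor <- function(cohort, config) {
  if (is.null(cohort$truth)) {
    stop("cohort carries no latent truth; simulate it with ",
         "simulate_trajectories()", call. = FALSE)
  }
  n <- length(cohort$ids)
  eta <- numeric(n)
  for (tm in config$hazard_terms) {
    x <- if (tm$feature == "fixed") {
      cohort$fixed[[tm$variable]]
    } else {
      tr <- cohort$truth[cohort$truth$variable == tm$variable, ]
      tr <- tr[match(cohort$ids, tr$participant_id), ]
      switch(tm$feature,
             slope = tr$slope,
             mean = tr$mean_level,
             class = as.numeric(tr$class == tm$class))
    }
    if (is.null(x) || anyNA(x)) {
      stop("hazard term on '", tm$variable, "' (", tm$feature,
           ") has no usable truth", call. = FALSE)
    }
    eta <- eta + tm$coef * (x - tm$center) / tm$scale
  }
  eta
}

#' Simulate the time-to-event outcome on the prediction window
#'
#' Event times are drawn from a Weibull process whose cumulative hazard
#' `(rate * t)^shape` is scaled by `exp(eta)` with `eta` the configured
#' linear predictor on trajectory-derived features. Observed time is the
#' minimum of the event time, an exponential dropout time, and the
#' administrative horizon.
#'
#' @param cohort A simulated cohort with truth attached.
#' @param config The [cohort_config()] used to simulate it.
#' @return Tibble with `participant_id`, `time_years` (years since the
#'   landmark, in `(0, admin_censor_years]`) and `event` (0/1), with the
#'   true linear predictor in attribute `"linpred"`.
#' @export
simulate_outcome <- function(cohort, config) {
  eta <- true_linear_predictor(cohort, config)
  set.seed(stage_seed(config$seed, "outcome"))
  n <- length(cohort$ids)
  u <- runif(n)
  t_event <- if (config$baseline_rate > 0) {
    (-log(u) * exp(-eta))^(1 / config$baseline_shape) / config$baseline_rate
  } else {
    rep(Inf, n)
  }
  t_cens <- if (config$random_censor_rate > 0) {
    rexp(n, config$random_censor_rate)
  } else {
    rep(Inf, n)
  }
  h <- config$admin_censor_years
  time <- pmin(t_event, t_cens, h)
  event <- as.integer(t_event <= pmin(t_cens, h))
  out <- tibble::tibble(participant_id = cohort$ids,
                        time_years = time, event = event)
  attr(out, "linpred") <- eta
  out
}

#' Last observation carried forward on a single series
#'
#' @param x Numeric vector, first element non-missing.
#' @return `x` with each `NA` replaced by the most recent preceding value.
#' @export
locf <- function(x) {
  if (length(x) && is.na(x[1])) {
    stop("LOCF needs a non-missing first observation", call. = FALSE)
  }
  keep <- !is.na(x)
  x[which(keep)][cumsum(keep)]
}

#' Mask cells at random and repair by LOCF
#'
#' Emulates sporadic missed measurements: each cell after the first visit is
#' masked independently with probability `missing_rate`, then refilled with
#' the participant's most recent preceding value of the same variable
#' (last observation carried forward). The first visit is never masked so
#' every series keeps its anchor; the returned grid is complete.
#'
#' @param cohort A `longitudinal_cohort`.
#' @param missing_rate Per-cell masking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `longitudinal_cohort` with the same shape and no missing cells.
#' @export
inject_missing_locf <- function(cohort, missing_rate, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (missing_rate == 0) return(cohort)
  set.seed(stage_seed(seed, "missing"))
  grids <- lapply(cohort$grids, function(m) {
    if (!nrow(m)) return(m)
    mask <- matrix(runif(length(m)) < missing_rate, nrow(m), ncol(m))
    mask[, 1] <- FALSE
    m[mask] <- NA_real_
    t(apply(m, 1, locf))
  })
  for (v in names(grids)) dimnames(grids[[v]]) <- dimnames(cohort$grids[[v]])
  new_cohort_from_grids(grids, cohort$visit_years, cohort$fixed,
                        cohort$truth)
}

#' Simulate a complete cohort: trajectories, missingness, outcome
#'
#' Convenience wrapper running [simulate_trajectories()],
#' [inject_missing_locf()] and [simulate_outcome()] with seeds derived from
#' the config seed.
#'
#' @param config A [cohort_config()].
#' @return List with elements `cohort` (complete grid) and `outcome`.
#' @export
simulate_cohort <- function(config) {
  cohort <- simulate_trajectories(config)
  cohort <- inject_missing_locf(cohort, config$missing_rate, config$seed)
  outcome <- simulate_outcome(cohort, config)
  list(cohort = cohort, outcome = outcome)
}
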