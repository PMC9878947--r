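#' Specify one longitudinal variable for the cohort simulator
#'
#' A variable is simulated from a small number of latent trajectory classes
#' (e.g. "low-stable", "high-increasing"). Each class is a linear-in-time
#' profile with optional curvature; binary variables are state sequences that
#' may switch once at a class-specific year; ordinal variables are rounded,
#' clamped latent continuous profiles.
#'
#' @param name Variable identifier.
#' @param kind One of `"continuous"`, `"binary"`, `"ordinal"`.
#' @param class_profiles A list of class profiles. For continuous/ordinal
#'   each is `list(intercept=, slope=, curvature=)` (curvature optional,
#'   per-year-squared). For binary each is
#'   `list(state0=, state1=, switch_time=)` where `switch_time = NA` means no
#'   switch (values in `{0,1}`).
#' @param class_probs Probability simplex over classes (must sum to 1).
#' @param noise_sd Within-person measurement noise SD (continuous/ordinal
#'   latent scale); ignored for binary.
#' @param ranef_intercept_sd,ranef_slope_sd SDs of per-person Gaussian random
#'   deviations around the class intercept and slope (continuous/ordinal).
#' @param levels For ordinal variables, the number of ordered levels.
#'
#' @return A `variable_spec` list.
#' @export
variable_spec <- function(name, kind = c("continuous", "binary", "ordinal"),
                          class_profiles, class_probs = NULL,
                          noise_sd = 0, ranef_intercept_sd = 0,
                          ranef_slope_sd = 0, levels = 5L) {
  kind <- match.arg(kind)
  if (is.null(class_probs)) {
    class_probs <- rep(1 / length(class_profiles), length(class_profiles))
  }
  if (length(class_probs) != length(class_profiles)) {
    stop("class_probs must have one entry per class profile", call. = FALSE)
  }
  if (any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-8) {
    stop("class_probs must be a probability simplex (non-negative, sum 1)",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(name = name, kind = kind, class_profiles = class_profiles,
         class_probs = class_probs, noise_sd = noise_sd,
         ranef_intercept_sd = ranef_intercept_sd,
         ranef_slope_sd = ranef_slope_sd, levels = as.integer(levels)),
    class = "variable_spec"
  )
}

#' One log-hazard term for the synthetic event process
#'
#' The simulated log-hazard is a sum of terms, each a coefficient times a
#' standardized trajectory-derived feature of one variable: the latent
#' per-person slope, the latent mean level over the data-collection window,
#' membership in a given latent class, or a time-fixed covariate.
#'
#' @param variable Variable name (a longitudinal variable, or a fixed
#'   covariate when `feature = "fixed"`).
#' @param feature One of `"slope"`, `"mean"`, `"class"`, `"fixed"`.
#' @param coef Log-hazard coefficient applied to `(x - center) / scale`.
#' @param class For `feature = "class"`, the 1-based latent class index whose
#'   indicator enters the hazard.
#' @param center,scale Standardization constants (population-level, chosen
#'   with the variable's specification).
#' @return A `hazard_term` list.
#' @export
hazard_term <- function(variable, feature = c("slope", "mean", "class", "fixed"),
                        coef, class = NA_integer_, center = 0, scale = 1) {
  feature <- match.arg(feature)
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  structure(list(variable = variable, feature = feature, coef = coef,
                 class = as.integer(class), center = center, scale = scale),
            class = "hazard_term")
}

#' Default longitudinal variable catalog
#'
#' 32 longitudinal variables emulating a young-adult cardiovascular cohort:
#' 20 continuous (blood pressure, lipids, glucose, anthropometry, alcohol
#' use, ...), 8 binary (smoking, anti-hypertensive medication, morbidity
#' history, ...) and 4 ordinal (physical activity, economic ability, ...).
#' A handful carry latent-class structure with per-person random slopes;
#' those slopes and levels are the features the default hazard acts on.
#'
#' @return A list of [variable_spec()] objects of length 32.
#' @export
default_variable_catalog <- function() {
  cont <- function(...) variable_spec(..., kind = "continuous")
  c(list(
    # signal-bearing continuous variables: multiple classes + random slopes
    cont("sbp",
         class_profiles = list(list(intercept = 108, slope = 0.10),
                               list(intercept = 113, slope = 0.30),
                               list(intercept = 118, slope = 1.20)),
         class_probs = c(0.4, 0.4, 0.2), noise_sd = 9,
         ranef_intercept_sd = 5, ranef_slope_sd = 0.25),
    cont("ldl",
         class_profiles = list(list(intercept = 100, slope = 0.20),
                               list(intercept = 135, slope = -1.00),
                               list(intercept = 118, slope = 1.50)),
         class_probs = c(0.5, 0.25, 0.25), noise_sd = 14,
         ranef_intercept_sd = 8, ranef_slope_sd = 0.30),
    cont("glucose",
         class_profiles = list(list(intercept = 82, slope = 0.20),
                               list(intercept = 85, slope = 1.00)),
         class_probs = c(0.75, 0.25), noise_sd = 9,
         ranef_intercept_sd = 5, ranef_slope_sd = 0.20),
    cont("bmi",
         class_profiles = list(list(intercept = 23.5, slope = 0.15),
                               list(intercept = 25.0, slope = 0.50)),
         class_probs = c(0.5, 0.5), noise_sd = 2,
         ranef_intercept_sd = 3, ranef_slope_sd = 0.10),
    # remaining continuous variables: level/trend structure, no hazard role
    cont("dbp",
         class_profiles = list(list(intercept = 66, slope = 0.20),
                               list(intercept = 72, slope = 0.45)),
         class_probs = c(0.6, 0.4), noise_sd = 6,
         ranef_intercept_sd = 5, ranef_slope_sd = 0.15),
    cont("hdl",
         class_profiles = list(list(intercept = 46, slope = -0.10),
                               list(intercept = 58, slope = 0.05)),
         class_probs = c(0.5, 0.5), noise_sd = 6,
         ranef_intercept_sd = 6, ranef_slope_sd = 0.15),
    cont("total_chol",
         class_profiles = list(list(intercept = 170, slope = 0.40),
                               list(intercept = 185, slope = 0.70)),
         class_probs = c(0.6, 0.4), noise_sd = 15,
         ranef_intercept_sd = 15, ranef_slope_sd = 0.30),
    cont("triglycerides",
         class_profiles = list(list(intercept = 65, slope = 1.20),
                               list(intercept = 90, slope = 2.50)),
         class_probs = c(0.7, 0.3), noise_sd = 20,
         ranef_intercept_sd = 15, ranef_slope_sd = 0.50),
    cont("pulse",
         class_profiles = list(list(intercept = 34, slope = 0.00),
                               list(intercept = 36, slope = 0.08)),
         class_probs = c(0.6, 0.4), noise_sd = 3,
         ranef_intercept_sd = 3, ranef_slope_sd = 0.05),
    cont("weight",
         class_profiles = list(list(intercept = 150, slope = 1.20),
                               list(intercept = 165, slope = 2.50)),
         class_probs = c(0.5, 0.5), noise_sd = 6,
         ranef_intercept_sd = 20, ranef_slope_sd = 0.40),
    cont("waist",
         class_profiles = list(list(intercept = 75, slope = 0.50),
                               list(intercept = 82, slope = 0.90)),
         class_probs = c(0.5, 0.5), noise_sd = 3,
         ranef_intercept_sd = 6, ranef_slope_sd = 0.15),
    cont("arm_circ",
         class_profiles = list(list(intercept = 28, slope = 0.20),
                               list(intercept = 31, slope = 0.30)),
         class_probs = c(0.5, 0.5), noise_sd = 1.5,
         ranef_intercept_sd = 2.5, ranef_slope_sd = 0.05),
    cont("education",
         class_profiles = list(list(intercept = 13, slope = 0.10),
                               list(intercept = 15, slope = 0.05)),
         class_probs = c(0.5, 0.5), noise_sd = 0.5,
         ranef_intercept_sd = 1.5, ranef_slope_sd = 0.02),
    cont("beer_week",
         class_profiles = list(list(intercept = 1.0, slope = -0.02),
                               list(intercept = 6.0, slope = -0.15)),
         class_probs = c(0.7, 0.3), noise_sd = 1.5,
         ranef_intercept_sd = 1.5, ranef_slope_sd = 0.05),
    cont("liquor_week",
         class_profiles = list(list(intercept = 0.5, slope = 0.00),
                               list(intercept = 2.5, slope = -0.05)),
         class_probs = c(0.75, 0.25), noise_sd = 0.8,
         ranef_intercept_sd = 0.8, ranef_slope_sd = 0.03),
    cont("wine_week",
         class_profiles = list(list(intercept = 0.6, slope = 0.03)),
         noise_sd = 0.8, ranef_intercept_sd = 0.8, ranef_slope_sd = 0.03),
    cont("cigs_day",
         class_profiles = list(list(intercept = 0.3, slope = 0.00),
                               list(intercept = 12, slope = -0.40)),
         class_probs = c(0.72, 0.28), noise_sd = 1.5,
         ranef_intercept_sd = 3, ranef_slope_sd = 0.10),
    cont("marijuana_freq",
         class_profiles = list(list(intercept = 2.0, slope = 0.01)),
         noise_sd = 0.6, ranef_intercept_sd = 1.0, ranef_slope_sd = 0.02),
    cont("times_pregnant",
         class_profiles = list(list(intercept = 0.5, slope = 0.06)),
         noise_sd = 0.3, ranef_intercept_sd = 0.8, ranef_slope_sd = 0.03),
    cont("pulse_pressure",
         class_profiles = list(list(intercept = 42, slope = 0.05),
                               list(intercept = 46, slope = 0.25)),
         class_probs = c(0.6, 0.4), noise_sd = 4,
         ranef_intercept_sd = 4, ranef_slope_sd = 0.10)
  ),
  list(
    # binary variables: state sequences with class-specific switch years
    variable_spec("smoking", "binary",
                  class_profiles = list(
                    list(state0 = 0, state1 = 0, switch_time = NA),
                    list(state0 = 1, state1 = 1, switch_time = NA),
                    list(state0 = 1, state1 = 0, switch_time = 7)),
                  class_probs = c(0.55, 0.25, 0.20)),
    variable_spec("htn_med", "binary",
                  class_profiles = list(
                    list(state0 = 0, state1 = 0, switch_time = NA),
                    list(state0 = 0, state1 = 1, switch_time = 5),
                    list(state0 = 0, state1 = 1, switch_time = 10)),
                  class_probs = c(0.90, 0.05, 0.05)),
    variable_spec("diabetes", "binary",
                  class_profiles = list(
                    list(state0 = 0, state1 = 0, switch_time = NA),
                    list(state0 = 0, state1 = 1, switch_time = 10)),
                  class_probs = c(0.94, 0.06)),
    variable_spec("kidney_problem", "binary",
                  class_profiles = list(
                    list(state0 = 0, state1 = 0, switch_time = NA),
                    list(state0 = 0, state1 = 1, switch_time = 7)),
                  class_probs = c(0.95, 0.05)),
    variable_spec("asthma", "binary",
                  class_profiles = list(
                    list(state0 = 0, state1 = 0, switch_time = NA),
                    list(state0 = 1, state1 = 1, switch_time = NA)),
                  class_probs = c(0.95, 0.05)),
    variable_spec("liver_problem", "binary",
                  class_profiles = list(
                    list(state0 = 0, state1 = 0, switch_time = NA),
                    list(state0 = 0, state1 = 1, switch_time = 10)),
                  class_probs = c(0.98, 0.02)),
    variable_spec("chol_med", "binary",
                  class_profiles = list(
                    list(state0 = 0, state1 = 0, switch_time = NA),
                    list(state0 = 0, state1 = 1, switch_time = 10)),
                  class_probs = c(0.97, 0.03)),
    variable_spec("parent_mi", "binary",
                  class_profiles = list(
                    list(state0 = 0, state1 = 0, switch_time = NA),
                    list(state0 = 0, state1 = 1, switch_time = 7),
                    list(state0 = 1, state1 = 1, switch_time = NA)),
                  class_probs = c(0.78, 0.08, 0.14)),
    # ordinal variables: rounded latent profiles
    variable_spec("activity", "ordinal",
                  class_profiles = list(list(intercept = 2.2, slope = 0.02),
                                        list(intercept = 4.0, slope = -0.05)),
                  class_probs = c(0.55, 0.45), noise_sd = 0.5,
                  ranef_intercept_sd = 0.5, ranef_slope_sd = 0.02,
                  levels = 5L),
    variable_spec("pay_basics", "ordinal",
                  class_profiles = list(list(intercept = 3.3, slope = 0.02),
                                        list(intercept = 2.0, slope = 0.00)),
                  class_probs = c(0.75, 0.25), noise_sd = 0.4,
                  ranef_intercept_sd = 0.4, ranef_slope_sd = 0.01,
                  levels = 4L),
    variable_spec("general_health", "ordinal",
                  class_profiles = list(list(intercept = 3.8, slope = -0.02),
                                        list(intercept = 2.5, slope = -0.05)),
                  class_probs = c(0.7, 0.3), noise_sd = 0.4,
                  ranef_intercept_sd = 0.5, ranef_slope_sd = 0.02,
                  levels = 5L),
    variable_spec("stress_level", "ordinal",
                  class_profiles = list(list(intercept = 2.0, slope = 0.03)),
                  noise_sd = 0.5, ranef_intercept_sd = 0.6,
                  ranef_slope_sd = 0.02, levels = 5L)
  ))
}

#' Default log-hazard structure for the synthetic event process
#'
#' The hazard is driven primarily by latent per-person trajectory slopes
#' (blood pressure, LDL cholesterol, glucose, adiposity), secondarily by mean
#' levels over the data-collection window, by sustained-smoker class
#' membership, and by the fixed demographics. Centers/scales are the
#' approximate population moments implied by [default_variable_catalog()],
#' so each term contributes roughly `coef^2` to the log-hazard variance.
#'
#' @return A list of [hazard_term()] objects.
#' @export
default_hazard_terms <- function() {
  list(
    hazard_term("sbp", "slope", coef = 0.55, center = 0.40, scale = 0.50),
    hazard_term("ldl", "slope", coef = 0.45, center = 0.23, scale = 0.93),
    hazard_term("glucose", "slope", coef = 0.35, center = 0.40, scale = 0.40),
    hazard_term("bmi", "slope", coef = 0.25, center = 0.33, scale = 0.20),
    hazard_term("sbp", "mean", coef = 0.22, center = 115.0, scale = 7.5),
    hazard_term("glucose", "mean", coef = 0.18, center = 85.6, scale = 7.0),
    hazard_term("smoking", "class", coef = 0.35, class = 2L, center = 0.25),
    hazard_term("age", "fixed", coef = 0.18, center = 25, scale = 3.6),
    hazard_term("sex_male", "fixed", coef = 0.25, center = 0.44, scale = 0.5)
  )
}

#' Configure a synthetic longitudinal cohort
#'
#' Bundles everything [simulate_trajectories()] and [simulate_outcome()]
#' need: the visit schedule of the data-collection window, the longitudinal
#' variable catalog with latent trajectory classes, fixed demographic
#' covariates, the log-hazard structure on trajectory-derived features, the
#' baseline event process on the prediction window, censoring, missingness,
#' and the seed.
#'
#' Defaults emulate a young-adult cardiovascular cohort: 6 exams over 15
#' years, 32 longitudinal + 3 fixed variables, a 17-year prediction window
#' with ~5% cumulative event rate, light random dropout, and <3% MCAR
#' missingness repaired by last-observation-carried-forward.
#'
#' @param n_participants Cohort size.
#' @param visit_years Strictly increasing exam times (years since
#'   enrollment); the last element is the landmark that starts the
#'   prediction window.
#' @param variables List of [variable_spec()]s.
#' @param hazard_terms List of [hazard_term()]s.
#' @param fixed_covariates Named list of time-fixed covariate generators,
#'   each `list("normal", mean, sd)` or `list("bernoulli", p)`.
#' @param baseline_rate Weibull scale-as-rate of the baseline event process:
#'   cumulative hazard `(baseline_rate * t)^baseline_shape`, so shape 1 is an
#'   exponential with this rate per year.
#' @param baseline_shape Weibull shape (1 = exponential, the default).
#' @param admin_censor_years Administrative horizon of the prediction window.
#' @param random_censor_rate Exponential dropout rate per year (0 disables).
#' @param missing_rate Per-cell MCAR masking probability (first visit never
#'   masked); repaired by LOCF.
#' @param seed Integer seed; the config is fully deterministic given it.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 2000,
                          visit_years = c(0, 2, 5, 7, 10, 15),
                          variables = default_variable_catalog(),
                          hazard_terms = default_hazard_terms(),
                          fixed_covariates = list(
                            age = list("normal", 25, 3.6),
                            sex_male = list("bernoulli", 0.44),
                            race_black = list("bernoulli", 0.47)),
                          baseline_rate = 0.0021,
                          baseline_shape = 1,
                          admin_censor_years = 17,
                          random_censor_rate = 0.008,
                          missing_rate = 0.02,
                          seed = 1L) {
  if (n_participants < 0) stop("n_participants must be >= 0", call. = FALSE)
  if (length(visit_years) < 2 || any(diff(visit_years) <= 0)) {
    stop("visit_years must be strictly increasing with length >= 2",
         call. = FALSE)
  }
  if (admin_censor_years <= 0) stop("admin_censor_years must be > 0",
                                    call. = FALSE)
  if (random_censor_rate < 0 || missing_rate < 0 || missing_rate >= 1) {
    stop("rates must be >= 0 and missing_rate < 1", call. = FALSE)
  }
  nm <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("variable names must be unique", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         visit_years = as.numeric(visit_years),
         variables = variables, hazard_terms = hazard_terms,
         fixed_covariates = fixed_covariates,
         baseline_rate = baseline_rate, baseline_shape = baseline_shape,
         admin_censor_years = admin_censor_years,
         random_censor_rate = random_censor_rate,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  kinds <- table(vapply(x$variables, `[[`, character(1), "kind"))
  cat("<cohort_config>\n",
      " participants: ", x$n_participants, "\n",
      " visits: ", paste(x$visit_years, collapse = ", "),
      " (landmark ", max(x$visit_years), "y)\n",
      " longitudinal variables: ", length(x$variables), " (",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), ")\n",
      " prediction window: ", x$admin_censor_years, "y, baseline rate ",
      x$baseline_rate, ", dropout rate ", x$random_censor_rate, "\n",
      " missing rate: ", x$missing_rate, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
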