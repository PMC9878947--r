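# Independent brute-force oracles, kept deliberately naive: each one
# re-derives its quantity from the definition, without touching the
# package's metric code paths.

# plain binary AUC by exhaustive pair comparison
oracle_binary_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Harrell's concordance restricted to earlier event times < tau, by
# exhaustive pair enumeration
oracle_harrell_c <- function(risk, time, event, tau = max(time)) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Kaplan-Meier survival by the product-limit definition
oracle_km <- function(time, status, at) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  for (u in ut) {
    if (u > at) break
    d <- sum(time == u & status == 1)
    r <- sum(time >= u)
    s <- s * (1 - d / r)
  }
  s
}

# Spearman correlation from the rank formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact Shapley values by subset enumeration; value function v(S) is the
# mean model output with features in S from the subject, rest from each
# background row in turn
oracle_exact_shapley <- function(f, x, background) {
  d <- length(x)
  stopifnot(d <= 12)
  vmem <- new.env()
  vfun <- function(S) {
    key <- paste0("k", paste(S, collapse = ","))
    if (!is.null(vmem[[key]])) return(vmem[[key]])
    vals <- apply(background, 1, function(b) {
      z <- b; z[S] <- x[S]; f(z)
    })
    vmem[[key]] <- mean(vals)
    vmem[[key]]
  }
  phi <- numeric(d)
  others <- function(j) setdiff(seq_len(d), j)
  for (j in seq_len(d)) {
    for (sz in 0:(d - 1)) {
      subs <- combn(others(j), sz, simplify = FALSE)
      w <- factorial(sz) * factorial(d - sz - 1) / factorial(d)
      for (S in subs) {
        phi[j] <- phi[j] + w * (vfun(sort(c(S, j))) - vfun(sort(S)))
      }
    }
  }
  phi
}

# adjusted Rand index between two labelings (pair-counting definition)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# small one-variable cohort builders used across test files ------------------

# cohort with one continuous variable following planted class profiles
make_planted_cohort <- function(n_per_class, profiles, visit_years,
                                noise_sd = 0, seed = 1) {
  set.seed(seed)
  k <- length(profiles)
  n <- n_per_class * k
  cls <- rep(seq_len(k), each = n_per_class)
  vals <- t(vapply(seq_len(n), function(i) {
    pr <- profiles[[cls[i]]]
    pr$intercept + pr$slope * visit_years +
      rnorm(length(visit_years), 0, noise_sd)
  }, numeric(length(visit_years))))
  ids <- sprintf("T%04d", seq_len(n))
  long <- tibble::tibble(
    participant_id = rep(ids, each = length(visit_years)),
    variable = "v1",
    visit_year = rep(visit_years, times = n),
    value = as.vector(t(vals)))
  cohort <- as_longitudinal_cohort(long, visit_years = visit_years)
  list(cohort = cohort, classes = cls, ids = ids)
}

# random uncensored outcome + scores for metric-oracle comparisons
random_uncensored_instance <- function(n) {
  tibble::tibble(
    participant_id = sprintf("U%03d", seq_len(n)),
    time_years = round(runif(n, 0.5, 20), 2),
    event = 1L)
}

# tiny simulated cohort configuration used by several suites
small_test_config <- function(n = 150, seed = 42, ...) {
  cohort_config(
    n_participants = n,
    variables = list(
      variable_spec("a", "continuous",
                    class_profiles = list(list(intercept = 0, slope = 0.2),
                                          list(intercept = 2, slope = 1)),
                    class_probs = c(0.5, 0.5), noise_sd = 0.3,
                    ranef_intercept_sd = 0.5, ranef_slope_sd = 0.1),
      variable_spec("b", "continuous",
                    class_profiles = list(list(intercept = 5, slope = -0.1)),
                    noise_sd = 0.5, ranef_intercept_sd = 1,
                    ranef_slope_sd = 0.05),
      variable_spec("s", "binary",
                    class_profiles = list(
                      list(state0 = 0, state1 = 0, switch_time = NA),
                      list(state0 = 1, state1 = 1, switch_time = NA)),
                    class_probs = c(0.7, 0.3))),
    hazard_terms = list(
      hazard_term("a", "slope", coef = 1, center = 0.6, scale = 0.4)),
    fixed_covariates = list(age = list("normal", 30, 4)),
    baseline_rate = 0.02, random_censor_rate = 0.01,
    missing_rate = 0, seed = seed, ...)
}
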