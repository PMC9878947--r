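# a deterministic risk function over a feature table (plug-in contract)
linear_risk_fn <- function(coefs) {
  function(ft) {
    m <- as.matrix(ft[names(coefs)])
    as.numeric(m %*% coefs)
  }
}

make_risk_data <- function(n = 150, d = 3, seed = 1, prefix = "f") {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0(prefix, seq_len(d))))
  ft <- feature_table(dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%04d", seq_len(n))),
    tibble::as_tibble(X)))
  ft
}

outcome_from_risk <- function(ft, risk, seed = 2, rate = 0.08) {
  set.seed(seed)
  n <- nrow(ft)
  t_ev <- rexp(n, rate * exp(risk))
  tibble::tibble(participant_id = ft$participant_id,
                 time_years = pmin(t_ev, 20),
                 event = as.integer(t_ev <= 20))
}

test_that("permutation importance ranks features by their true effect", {
  ft <- make_risk_data(n = 300, d = 3, seed = 11)
  f <- linear_risk_fn(c(f1 = 2, f2 = 1, f3 = 0))
  out <- outcome_from_risk(ft, f(ft), seed = 12)
  imp <- permutation_importance(f, ft, out, n_perm = 20, seed = 5)
  scores <- setNames(imp$importance, imp$feature)
  expect_equal(unname(which.max(scores[c("f1", "f2", "f3")])), 1)
  expect_equal(max(imp$importance), 1)
  expect_gt(scores["f1"], scores["f2"])
  expect_gt(scores["f2"], scores["f3"])
  expect_lt(abs(imp$raw[imp$feature == "f3"]), 0.02)
})

test_that("a model that is a monotone function of one feature puts it first", {
  ft <- make_risk_data(n = 200, d = 4, seed = 13)
  f <- function(tbl) exp(tbl$f2)
  out <- outcome_from_risk(ft, log(f(ft)), seed = 14)
  imp <- permutation_importance(f, ft, out, n_perm = 15, seed = 6)
  expect_equal(imp$feature[which.max(imp$importance)], "f2")
  expect_equal(max(imp$importance), 1)
})

test_that("sampling Shapley matches exact enumeration on small models", {
  set.seed(21)
  d <- 5
  bg <- make_risk_data(n = 25, d = d, seed = 21)
  coefs <- c(f1 = 0.8, f2 = -0.5, f3 = 0.3, f4 = 0, f5 = 1.1)
  # nonlinear term keeps the game non-trivial
  f_vec <- function(x) sum(coefs * x) + 0.5 * x[1] * x[1]
  f_ft <- function(ft) {
    m <- as.matrix(ft[paste0("f", 1:d)])
    as.numeric(m %*% coefs + 0.5 * m[, 1]^2)
  }
  subj <- trajsurv:::ft_rows(bg, bg$participant_id[3])
  res <- shapley_sampling(f_ft, subj, bg, horizon = 10,
                          n_samples = 3000, seed = 9)
  exact <- oracle_exact_shapley(f_vec, as.numeric(subj[1, paste0("f", 1:d)]),
                                trajsurv:::ft_matrix(bg))
  expect_lt(max(abs(res$phi - exact)), 0.01)
  # efficiency: adjusted contributions sum exactly to pred - base
  expect_equal(sum(res$phi_adjusted),
               attr(res, "prediction") - attr(res, "base_value"),
               tolerance = 1e-12)
  # pre-adjustment residual is within sampling noise
  expect_lt(abs(sum(res$phi) -
                  (attr(res, "prediction") - attr(res, "base_value"))),
            2 / sqrt(3000) * 5)
})

test_that("additive models attribute each feature its centered effect", {
  d <- 4
  bg <- make_risk_data(n = 40, d = d, seed = 22)
  coefs <- c(f1 = 1, f2 = 2, f3 = -1, f4 = 0.5)
  f_ft <- linear_risk_fn(coefs)
  subj <- trajsurv:::ft_rows(bg, bg$participant_id[1])
  res <- shapley_sampling(f_ft, subj, bg, horizon = 5,
                          n_samples = 2000, seed = 10)
  xs <- as.numeric(subj[1, paste0("f", 1:d)])
  bg_means <- colMeans(trajsurv:::ft_matrix(bg))
  expect_lt(max(abs(res$phi - unname(coefs * (xs - bg_means)))), 0.02)
})

test_that("single-feature models receive the entire attribution", {
  bg <- make_risk_data(n = 30, d = 1, seed = 23)
  f_ft <- linear_risk_fn(c(f1 = 2))
  subj <- trajsurv:::ft_rows(bg, bg$participant_id[5])
  res <- shapley_sampling(f_ft, subj, bg, horizon = 5, n_samples = 50,
                          seed = 3)
  expect_equal(res$phi_adjusted,
               attr(res, "prediction") - attr(res, "base_value"),
               tolerance = 1e-12)
  expect_error(shapley_sampling(f_ft, subj, bg, 5, n_samples = 0),
               "n_samples")
})

test_that("cluster partial dependence isolates the planted cluster effect", {
  set.seed(31)
  n <- 300
  cl <- sample(1:3, n, replace = TRUE)
  other <- rnorm(n)
  # cluster 3 is harmful
  risk <- 1.2 * (cl == 3) + 0.3 * other
  ft <- feature_table(
    tibble::tibble(participant_id = sprintf("P%04d", 1:n),
                   v__cluster = as.numeric(cl), other = other))
  out <- outcome_from_risk(ft, risk, seed = 32, rate = 0.05)
  fit <- fit_survival_model(ft, out, model_spec("coxph"))
  pdp <- partial_dependence_clusters(fit, ft, "v", time_grid = c(5, 10, 15))
  wide <- tidyr::pivot_wider(pdp, names_from = "cluster",
                             values_from = "survival")
  late <- wide[wide$time > 0, ]
  expect_true(all(late$`3` < late$`1`))
  expect_true(all(late$`3` < late$`2`))
  # a model ignoring the variable yields identical curves
  ft0 <- ft; risk0 <- 0.3 * other
  out0 <- outcome_from_risk(ft0, risk0, seed = 33, rate = 0.05)
  f_ignore <- function(tbl) 0.3 * tbl$other
  pdp0 <- partial_dependence_clusters(
    structure(list(family = "coxph",
                   columns = c("v__cluster", "other"),
                   state = list(beta = c(v__cluster = 0, other = 0.3),
                                used = c("v__cluster", "other")),
                   baseline = list(time = c(5, 10), cumhaz = c(0.1, 0.2))),
              class = "trajsurv_model"),
    ft0, "v", k = 3, time_grid = c(5, 10))
  w0 <- tidyr::pivot_wider(pdp0, names_from = "cluster",
                           values_from = "survival")
  expect_equal(w0$`1`, w0$`2`)
  expect_equal(w0$`2`, w0$`3`)
})

# --- temporal-window importance ---------------------------------------------

make_concat_cohort <- function(n = 250, seed = 41,
                               sched = c(0, 2, 5, 7, 10, 15)) {
  # independent visit values: every visit carries an equal share of any
  # aggregate functional, so minimal windows are unambiguous
  set.seed(seed)
  p <- length(sched)
  ids <- sprintf("P%04d", 1:n)
  grids <- list(va = matrix(rnorm(n * p), n, p),
                vb = matrix(rnorm(n * p), n, p))
  for (g in names(grids)) dimnames(grids[[g]]) <- list(ids, sched)
  co <- trajsurv:::new_cohort_from_grids(grids, sched)
  featurize_concatenated(co)
}

test_that("TIME pins a single-visit model to its visit and zeroes the rest", {
  ft <- make_concat_cohort()
  f <- function(tbl) tbl$va__y15
  out <- outcome_from_risk(ft, f(ft), seed = 42, rate = 0.06)
  ti <- time_importance(f, ft, out, time_config(n_permutations = 100,
                                                seed = 7))
  row_a <- ti[ti$variable == "va", ]
  row_b <- ti[ti$variable == "vb", ]
  expect_equal(row_a$importance, 1)
  expect_equal(c(row_a$window_start, row_a$window_end), c(6, 6))
  expect_lt(row_b$importance, 0.05)
  expect_true(is.na(row_b$window_start))
  cells <- attr(ti, "cells")
  expect_equal(unname(which.max(cells["va", ])), 6)
})

test_that("TIME: a mean-functional model spans all visits, ordering irrelevant", {
  ft <- make_concat_cohort(seed = 43)
  cols <- grep("^va__", names(ft), value = TRUE)
  f <- function(tbl) rowMeans(as.matrix(tbl[cols]))
  out <- outcome_from_risk(ft, 2 * f(ft), seed = 44, rate = 0.06)
  ti <- time_importance(f, ft, out, time_config(n_permutations = 100,
                                                seed = 8))
  row_a <- ti[ti$variable == "va", ]
  expect_equal(c(row_a$window_start, row_a$window_end), c(1, 6))
  expect_false(row_a$ordering_matters)
})

test_that("TIME: a slope-functional model spans all visits and ordering matters", {
  # three equally spaced visits: the per-subject OLS slope weights the
  # endpoints equally, so no sub-window captures 90% of the importance
  sched <- c(0, 1, 2)
  ft <- make_concat_cohort(seed = 45, sched = sched)
  cols <- grep("^va__", names(ft), value = TRUE)
  f <- function(tbl) {
    m <- as.matrix(tbl[cols])
    tc <- sched - mean(sched)
    as.numeric(m %*% tc) / sum(tc^2)
  }
  out <- outcome_from_risk(ft, 2 * f(ft), seed = 46, rate = 0.06)
  ti <- time_importance(f, ft, out, time_config(n_permutations = 100,
                                                seed = 9))
  row_a <- ti[ti$variable == "va", ]
  expect_equal(c(row_a$window_start, row_a$window_end), c(1, 3))
  expect_true(row_a$ordering_matters)
})

test_that("explainers leave the model untouched", {
  ft <- make_risk_data(n = 120, d = 2, seed = 51)
  risk <- linear_risk_fn(c(f1 = 1, f2 = 0.5))
  out <- outcome_from_risk(ft, risk(ft), seed = 52)
  fit <- fit_survival_model(ft, out, model_spec("coxph"))
  snapshot <- unserialize(serialize(fit, NULL))
  invisible(permutation_importance(fit, ft, out, n_perm = 3, seed = 1))
  invisible(shapley_sampling(fit, trajsurv:::ft_rows(ft, ft$participant_id[1]),
                             ft, horizon = 10, n_samples = 20, seed = 1))
  expect_equal(fit, snapshot)
})
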