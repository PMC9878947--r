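test_that("censoring KM weights reduce to 1 without censoring and match hand KM", {
  out <- tibble::tibble(participant_id = letters[1:5],
                        time_years = c(1, 2, 3, 4, 5),
                        event = rep(1L, 5))
  G <- censoring_km(out)
  expect_equal(trajsurv:::G_at(G, c(0, 2.5, 5)), c(1, 1, 1))
  # one censoring at 5 among 5 at risk: G drops by the product-limit factor
  out2 <- tibble::tibble(participant_id = letters[1:5],
                         time_years = c(6, 7, 5, 8, 9),
                         event = c(1L, 1L, 0L, 1L, 1L))
  G2 <- censoring_km(out2)
  manual <- oracle_km(out2$time_years, 1 - out2$event, 5)
  expect_equal(trajsurv:::G_at(G2, 5), manual)
  expect_equal(manual, 1 - 1 / 5)
  # all censored at the same time: G steps to 0 there, and horizons beyond
  # the follow-up have no cases or controls -> NA sentinel
  out3 <- tibble::tibble(participant_id = letters[1:4],
                         time_years = rep(3, 4), event = rep(0L, 4))
  G3 <- censoring_km(out3)
  expect_equal(trajsurv:::G_at(G3, 3), 0)
  expect_true(is.na(time_dependent_auc(c(1, 2, 3, 4), out3, horizon = 4,
                                       G3)))
  # subjects censored exactly at the horizon are event-free controls,
  # weighted by G(horizon-)
  out4 <- tibble::tibble(participant_id = letters[1:5],
                         time_years = c(1, 2, 5, 5, 5),
                         event = c(1L, 1L, 0L, 0L, 0L))
  a4 <- time_dependent_auc(c(5, 4, 1, 2, 3), out4, horizon = 5)
  expect_equal(a4, 1)
})

test_that("uncensored IPCW metrics equal their brute-force counterparts", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(20:60, 1)
    out <- random_uncensored_instance(n)
    risk <- rnorm(n)
    if (rep %% 3 == 0) risk <- round(risk, 1)  # induce ties
    h <- quantile(out$time_years, runif(1, 0.3, 0.8), names = FALSE)
    G <- censoring_km(out)
    # time-dependent AUC == binary AUC of event-by-horizon status
    expect_equal(time_dependent_auc(risk, out, h, G),
                 oracle_binary_auc(risk, as.integer(out$time_years <= h)),
                 tolerance = 1e-10)
    # truncated C == exhaustive-pair Harrell's C
    expect_equal(truncated_cindex(risk, out, tau = h, G),
                 oracle_harrell_c(risk, out$time_years, out$event, h),
                 tolerance = 1e-10)
    # Brier == plain MSE of (alive indicator - S)
    S <- runif(n)
    curves <- structure(list(ids = out$participant_id,
                             time_grid = c(0, h),
                             probs = cbind(1, S)),
                        class = "surv_curves")
    mse <- mean(((out$time_years > h) - S)^2)
    expect_equal(brier_score(curves, out, h, G), mse, tolerance = 1e-10)
  }
})

test_that("AUC boundary behaviour: perfect ranking, antisymmetry, degenerate cases", {
  out <- random_uncensored_instance(20)
  h <- median(out$time_years)
  case <- out$time_years <= h
  risk <- ifelse(case, 1, 0) + runif(20, 0, 0.01) * ifelse(case, 1, -1)
  expect_equal(time_dependent_auc(risk, out, h), 1)
  r2 <- rnorm(20)
  expect_equal(time_dependent_auc(-r2, out, h),
               1 - time_dependent_auc(r2, out, h), tolerance = 1e-12)
  expect_true(is.na(time_dependent_auc(r2, out, max(out$time_years) + 1)))
})

test_that("truncated concordance is 1 for monotone risk and 0.5 under independence", {
  out <- random_uncensored_instance(40)
  risk <- -out$time_years  # perfectly anti-monotone in time
  expect_equal(truncated_cindex(risk, out), 1)
  set.seed(5)
  vals <- replicate(200, {
    o <- random_uncensored_instance(40)
    truncated_cindex(rnorm(40), o)
  })
  expect_lt(abs(mean(vals) - 0.5), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("Brier score sanity: oracle predictions score 0, coin-flip scores 0.25", {
  out <- random_uncensored_instance(30)
  h <- median(out$time_years)
  alive <- as.numeric(out$time_years > h)
  oracle_curves <- structure(list(ids = out$participant_id,
                                  time_grid = c(0, h),
                                  probs = cbind(1, alive)),
                             class = "surv_curves")
  expect_equal(brier_score(oracle_curves, out, h), 0)
  half <- structure(list(ids = out$participant_id, time_grid = c(0, h),
                         probs = cbind(1, rep(0.5, 30))),
                    class = "surv_curves")
  expect_equal(brier_score(half, out, h), 0.25)
})

test_that("integrated AUC is a normalized density-weighted mean", {
  # constant AUC integrates to itself
  out <- random_uncensored_instance(50)
  grid <- c(2, 5, 8, 12)
  expect_equal(integrated_auc(rep(0.73, 4), grid, out), 0.73)
  # hand-set masses
  expect_equal(integrated_auc(c(0.6, 0.8), c(5, 10),
                              weights = c(0.25, 0.75)), 0.75)
  # module weights equal brute-force KM increments
  w <- event_density_weights(out, grid)
  manual <- -diff(vapply(c(0, grid), function(g) {
    oracle_km(out$time_years, out$event, g)
  }, 1))
  expect_equal(unname(w), unname(manual), tolerance = 1e-12)
})

test_that("classification at the F1-optimal cutoff matches confusion arithmetic", {
  # hand-built 2x2: 10 cases (8 above cutoff), 90 controls (2 above)
  out <- tibble::tibble(
    participant_id = sprintf("C%03d", 1:100),
    time_years = c(rep(1, 10), rep(10, 90)),
    event = c(rep(1L, 10), rep(0L, 90)))
  risk <- c(rep(0.9, 8), rep(0.1, 2),   # TP=8, FN=2
            rep(0.9, 2), rep(0.1, 88))  # FP=2, TN=88
  cls <- classification_at_horizon(risk, out, horizon = 5)
  expect_equal(cls$f1, 0.8)
  expect_equal(cls$sensitivity, 0.8)
  expect_equal(cls$specificity, 88 / 90)
  mcc_manual <- (8 * 88 - 2 * 2) / sqrt(10 * 10 * 90 * 90)
  expect_equal(cls$mcc, mcc_manual)
  # perfect separation
  risk2 <- c(rep(1, 10), rep(0, 90))
  cls2 <- classification_at_horizon(risk2, out, horizon = 5)
  expect_equal(unlist(cls2[c("sensitivity", "specificity", "ppv", "npv",
                             "f1", "mcc")]),
               rep(1, 6), ignore_attr = TRUE)
  # the lowest cutoff classifies everyone positive
  low <- min(risk)
  tp_all <- classification_at_horizon(risk, out, 5)
  expect_true(tp_all$cutoff >= low)
  # degenerate single-class input returns sentinels
  out_deg <- tibble::tibble(participant_id = c("a", "b"),
                            time_years = c(10, 12), event = c(0L, 0L))
  expect_true(all(is.na(classification_at_horizon(c(0.1, 0.2), out_deg,
                                                  5))))
})

test_that("bounded metrics respect their ranges on randomized inputs", {
  set.seed(77)
  for (i in 1:25) {
    n <- 50
    out <- tibble::tibble(
      participant_id = sprintf("R%02d", 1:n),
      time_years = round(rexp(n, 0.1) + 0.1, 2),
      event = rbinom(n, 1, 0.6))
    risk <- rnorm(n)
    h <- quantile(out$time_years, 0.5, names = FALSE)
    G <- censoring_km(out)
    a <- time_dependent_auc(risk, out, h, G)
    cc <- truncated_cindex(risk, out, h, G)
    if (!is.na(a)) expect_true(a >= 0 && a <= 1)
    if (!is.na(cc)) expect_true(cc >= 0 && cc <= 1)
    cls <- classification_at_horizon(risk, out, h, G)
    if (!is.na(cls$mcc)) expect_true(abs(cls$mcc) <= 1)
  }
})
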