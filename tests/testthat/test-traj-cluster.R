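test_that("summary measures match hand-computed values", {
  t3 <- c(0, 1, 2)
  m <- traj_summary_measures(c(1, 5, 3), t3)
  expect_equal(unname(m["range"]), 4)
  expect_equal(unname(m["total_change"]), 2)
  m2 <- traj_summary_measures(c(2, 9, 7), t3)
  expect_equal(unname(m2["total_change"]), 5)
  # noiseless linear series: perfect fit and exact slope
  m3 <- traj_summary_measures(c(1, 3, 7, 11), c(0, 1, 3, 5))
  expect_equal(unname(m3["rsq"]), 1)
  expect_equal(unname(m3["slope"]), 2)
  expect_length(m, 24)
  expect_false(anyNA(m))
  # zero-variance series: zero-denominator measures take the 0 sentinel
  mz <- traj_summary_measures(c(0, 0, 0), t3)
  expect_false(anyNA(mz))
  expect_equal(unname(mz["cv"]), 0)
})

test_that("factor selection recovers planted independent dimensions", {
  set.seed(7)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  M <- cbind(f1 + rnorm(n, 0, 0.05), f1 * 2 + rnorm(n, 0, 0.05),
             f2 + rnorm(n, 0, 0.05), -f2 + rnorm(n, 0, 0.05))
  colnames(M) <- paste0("m", 1:4)
  sel <- factor_select_measures(M)
  expect_length(sel, 2)
  expect_equal(attr(sel, "n_factors"), 2)
  # one selected measure loads on each latent dimension
  picked <- M[, sel]
  cors <- abs(cor(cbind(f1, f2), picked))
  expect_true(all(apply(cors, 2, max) > 0.9))
  expect_equal(unname(sort(apply(cors, 2, which.max))), c(1, 2))
})

test_that("rank-one measure matrices collapse to a single selection", {
  set.seed(8)
  base <- rnorm(50)
  M <- cbind(base, base, base, base)
  sel <- factor_select_measures(M + matrix(rnorm(200, 0, 1e-8), 50))
  expect_length(sel, 1)
})

test_that("block-diagonal correlation yields one measure per block", {
  set.seed(9)
  n <- 400
  blocks <- replicate(3, rnorm(n))
  M <- cbind(blocks[, 1] + rnorm(n, 0, 0.1),
             blocks[, 1] - rnorm(n, 0, 0.1),
             blocks[, 2] + rnorm(n, 0, 0.1),
             blocks[, 2] * 1.5 + rnorm(n, 0, 0.1),
             blocks[, 3] + rnorm(n, 0, 0.1),
             blocks[, 3] * -2 + rnorm(n, 0, 0.1))
  sel <- factor_select_measures(M)
  expect_length(sel, 3)
  block_of <- apply(abs(cor(blocks, M[, sel])), 2, which.max)
  expect_setequal(block_of, 1:3)
})

test_that("criterion vote picks the planted cluster count and breaks ties low", {
  set.seed(12)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(120, 0, 0.4), 60, 2), 2, centers[k, ], "+")
  }))
  k <- select_cluster_count(X, k_range = 2:6, seed = 5)
  expect_equal(as.integer(k), 3)
  expect_true(all(attr(k, "votes") == 3))
})

test_that("planted trajectory classes are recovered by clustering", {
  profiles <- list(list(intercept = 95, slope = 0.1),    # low-stable
                   list(intercept = 140, slope = -1.6),  # high-decreasing
                   list(intercept = 120, slope = 1.8))   # high-increasing
  sched <- c(0, 2, 5, 7, 10, 15)
  # noiseless: perfectly separable, exact recovery
  p0 <- make_planted_cohort(40, profiles, sched, noise_sd = 0, seed = 2)
  cm0 <- cluster_trajectories(p0$cohort, "v1", k = 3, seed = 3)
  expect_equal(oracle_ari(cm0$memberships$cluster, p0$classes), 1)
  # moderate noise: near-perfect recovery with k chosen by vote
  p1 <- make_planted_cohort(60, profiles, sched, noise_sd = 4, seed = 4)
  cm1 <- cluster_trajectories(p1$cohort, "v1", seed = 3)
  expect_equal(cm1$k, 3)
  expect_gte(oracle_ari(cm1$memberships$cluster, p1$classes), 0.9)
  # agrees with the independent pair-counting ARI from mclust
  expect_equal(oracle_ari(cm1$memberships$cluster, p1$classes),
               mclust::adjustedRandIndex(cm1$memberships$cluster,
                                         p1$classes))
})

test_that("canonical relabeling is invariant to initialization order", {
  profiles <- list(list(intercept = 95, slope = 0.1),   # low-stable
                   list(intercept = 140, slope = -1.6), # high-decreasing
                   list(intercept = 120, slope = 1.8))  # high-increasing
  p <- make_planted_cohort(30, profiles, c(0, 2, 5, 7, 10, 15),
                           noise_sd = 3, seed = 6)
  m1 <- cluster_trajectories(p$cohort, "v1", k = 3, seed = 1)
  m2 <- cluster_trajectories(p$cohort, "v1", k = 3, seed = 99)
  expect_equal(m1$memberships$cluster, m2$memberships$cluster)
  expect_gte(oracle_ari(m1$memberships$cluster, p$classes), 0.9)
  # labels ordered by ascending within-cluster mean level: the low-stable
  # class maps to cluster 1
  maj <- function(cl) as.integer(names(which.max(table(cl))))
  expect_equal(maj(m1$memberships$cluster[p$classes == 1]), 1L)
})

test_that("a degenerate single-class variable still returns memberships", {
  p <- make_planted_cohort(25, list(list(intercept = 5, slope = 0)),
                           c(0, 1, 2), noise_sd = 0, seed = 7)
  expect_warning(cm <- cluster_trajectories(p$cohort, "v1", seed = 1),
                 "distinct")
  expect_true(all(cm$memberships$cluster >= 1))
})

test_that("out-of-sample cluster assignment uses nearest training centroid", {
  profiles <- list(list(intercept = 95, slope = 0.1),
                   list(intercept = 140, slope = -1.6),
                   list(intercept = 120, slope = 1.8))
  p <- make_planted_cohort(50, profiles, c(0, 2, 5, 7, 10, 15),
                           noise_sd = 3, seed = 8)
  train <- p$ids[c(1:35, 51:85, 101:135)]
  test <- setdiff(p$ids, train)
  cm <- cluster_trajectories(p$cohort, "v1", ids = train, k = 3, seed = 1)
  # contract: assignment is by nearest centroid, so re-predicting the
  # training ids reproduces the stored memberships
  back <- predict_clusters(cm, p$cohort, train)
  expect_equal(unname(back), cm$memberships$cluster)
  # held-out participants land in the cluster of their planted class
  pred <- predict_clusters(cm, p$cohort, test)
  truth_test <- p$classes[match(test, p$ids)]
  expect_gte(oracle_ari(pred, truth_test), 0.9)
})

test_that("cluster featurization produces one membership column per variable", {
  cfg <- small_test_config(n = 60, seed = 15)
  co <- simulate_trajectories(cfg)
  ft <- featurize_clusters(co, seed = 2, k_range = 2:3,
                           criteria = c("wss", "silhouette", "ch"))
  expect_setequal(setdiff(names(ft), "participant_id"),
                  c("a__cluster", "b__cluster", "s__cluster", "age"))
  expect_true(all(ft$a__cluster >= 1))
  models <- attr(ft, "cluster_models")
  expect_s3_class(models$a, "traj_cluster_model")
})
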