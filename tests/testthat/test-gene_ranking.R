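test_that("anova_f matches the closed form and flags degenerate genes", {
  X <- rbind(shift = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
             flat = c(1, 2, 3, 1, 2, 3, 1, 2, 3),
             const = rep(5, 9))
  colnames(X) <- paste0("s", 1:9)
  y <- tiny_labels(c("a", "b", "c"), 3)
  names(y) <- colnames(X)
  res <- anova_f(X, y)
  expect_equal(unname(res$f["shift"]), 3.0, tolerance = 1e-12)
  expect_equal(unname(res$f["flat"]), 0)       # identical group means
  expect_equal(unname(res$f["const"]), 0)      # 0/0 convention
  expect_identical(unname(res$degenerate), c(FALSE, FALSE, TRUE))
})

test_that("anova_f agrees with a two-pass sums-of-squares oracle", {
  set.seed(31)
  n <- 24
  y <- tiny_labels(c("a", "b", "c"), 8)
  X <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(sprintf("g%02d", 1:50), names(y)))
  res <- anova_f(X, y)
  for (g in rownames(X)) {
    expect_equal(unname(res$f[g]), anova_oracle(X[g, ], y), tolerance = 1e-10)
  }
})

test_that("anova_f is invariant to sample permutation", {
  ds <- simulate_expression(sim_config(p = 30, n_per_class = 8,
                                       n_informative = 5, seed = 2))
  perm <- sample(ncol(ds$matrix))
  a <- anova_f(ds$matrix, ds$labels)$f
  b <- anova_f(ds$matrix[, perm], ds$labels[perm])$f
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("label correlation has exact values for constructed genes", {
  y <- tiny_labels(c("OVT", "OVC_I", "OVC_III"), 4)
  coded <- c(OVT = 0, OVC_I = 1, OVC_III = 2)[as.character(y)]
  X <- rbind(up = as.numeric(coded) + 0,
             down = -as.numeric(coded),
             dead = rep(1, 12))
  colnames(X) <- names(y)
  R <- correlation_with_label(X, y)
  expect_equal(unname(R["up", "label"]), 1.0)
  expect_equal(unname(R["down", "label"]), -1.0)
  expect_true(is.na(R["dead", "label"]))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_equal(R, t(R))
})

test_that("independent noise genes decorrelate at large n", {
  set.seed(77)
  n <- 1000
  y <- tiny_labels(c("a", "b"), n / 2)
  X <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("g1", "g2"), names(y)))
  R <- correlation_with_label(X, y)
  expect_lt(abs(R["g1", "g2"]), 0.1)
})

test_that("rfe with target_size = p returns everything with an empty trace", {
  ds <- simulate_expression(sim_config(p = 15, n_per_class = 6,
                                       n_informative = 3, seed = 4))
  r <- rfe_rank(ds$matrix, ds$labels, learner_spec("xgboost_like", seed = 1),
                target_size = 15)
  expect_setequal(r$gene_ids, rownames(ds$matrix))
  expect_length(r$elimination_trace, 0)
  expect_true(all(diff(unname(r$scores)) <= 1e-12))
})

test_that("a strongly planted gene survives elimination across seeds", {
  survived <- sapply(1:5, function(s) {
    ds <- simulate_expression(sim_config(p = 20, n_per_class = 30,
                                         n_informative = 1, effect = 3, seed = s))
    r <- rfe_rank(ds$matrix, ds$labels,
                  learner_spec("xgboost_like", seed = s), target_size = 5)
    ds$truth %in% r$gene_ids
  })
  expect_gte(sum(survived), 4)
})

test_that("block elimination matches one-at-a-time elimination when importances are well separated", {
  # genes with strictly decreasing effect sizes give a stable importance order
  set.seed(12)
  n <- 90
  y <- tiny_labels(c("a", "b", "c"), 30)
  effects <- c(6, 5, 4, 3, 2, 0, 0, 0, 0, 0)
  X <- t(sapply(effects, function(e) {
    as.numeric(y) * e + rnorm(n)
  }))
  dimnames(X) <- list(sprintf("g%02d", 1:10), names(y))
  sp <- learner_spec("xgboost_like", seed = 5)
  blockwise <- rfe_rank(X, y, sp, target_size = 3, step_fraction = 0.3)
  one_by_one <- rfe_rank(X, y, sp, target_size = 3, step_fraction = 1e-6)
  expect_setequal(blockwise$gene_ids, one_by_one$gene_ids)
})

test_that("rfe respects its trace invariant and input validation", {
  ds <- simulate_expression(sim_config(p = 12, n_per_class = 6,
                                       n_informative = 2, seed = 8))
  r <- rfe_rank(ds$matrix, ds$labels, learner_spec("gbdt", seed = 2),
                target_size = 4, step_fraction = 0.25)
  removed <- unlist(r$elimination_trace)
  expect_setequal(c(removed, r$gene_ids), rownames(ds$matrix))
  expect_length(intersect(removed, r$gene_ids), 0)
  expect_error(rfe_rank(ds$matrix, ds$labels, learner_spec("gbdt"),
                        target_size = 99), "target_size")
  y1 <- ds$labels; y1[] <- "OVT"
  expect_error(rfe_rank(ds$matrix, y1, learner_spec("gbdt"), target_size = 4),
               "classes")
})

test_that("each learner kind is locked to its importance criterion", {
  expect_identical(learner_spec("gbdt")$importance_criterion, "weight")
  expect_identical(learner_spec("catboost_like")$importance_criterion,
                   "prediction_value_change")
  expect_identical(learner_spec("xgboost_like")$importance_criterion, "gain")
})
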