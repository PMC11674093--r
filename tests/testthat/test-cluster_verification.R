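test_that("well-separated clouds are recovered exactly by both methods", {
  set.seed(41)
  X <- cbind(matrix(rnorm(5 * 10, mean = 0), 5, 10),
             matrix(rnorm(5 * 10, mean = 20), 5, 10))
  dimnames(X) <- list(paste0("g", 1:5), paste0("s", 1:20))
  truth <- rep(0:1, each = 10)
  for (method in c("kmeans", "agglomerative")) {
    cl <- cluster_samples(X, 2, method = method, seed = 1)
    expect_identical(unname(cl$assignments), truth)
  }
})

test_that("K = n gives singleton clusters with purity 1", {
  set.seed(42)
  X <- matrix(rnorm(3 * 8), 3, 8,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  y <- tiny_labels(c("a", "b"), 4)
  names(y) <- colnames(X)
  cl <- cluster_samples(X, 8, method = "kmeans", seed = 2)
  expect_identical(sort(unique(unname(cl$assignments))), 0:7)
  v <- align_and_score(cl$assignments, y)
  expect_equal(v$purity, 1)
})

test_that("ward agglomerative matches k-means on three separated gaussians", {
  set.seed(43)
  mu <- c(0, 15, 30)
  X <- do.call(cbind, lapply(mu, function(m) matrix(rnorm(4 * 10, mean = m), 4, 10)))
  dimnames(X) <- list(paste0("g", 1:4), paste0("s", 1:30))
  km <- cluster_samples(X, 3, method = "kmeans", seed = 3)
  ag <- cluster_samples(X, 3, method = "agglomerative", linkage = "ward", seed = 3)
  expect_equal(mclust::adjustedRandIndex(km$assignments, ag$assignments), 1)
})

test_that("a diagonal stage-level confusion scores purity 1 and ARI 1", {
  assignments <- stats::setNames(rep(0:2, each = 5), paste0("s", 1:15))
  y <- factor(rep(c("OVT", "OVC_I", "OVC_III"), each = 5),
              levels = c("OVT", "OVC_I", "OVC_III"))
  names(y) <- names(assignments)
  v <- align_and_score(assignments, y)
  expect_equal(v$purity, 1)
  expect_equal(v$accuracy, 1)
  expect_equal(v$ari, 1)
  expect_identical(unname(diag(v$confusion)), rep(5L, 3))
})

test_that("a single catch-all cluster of balanced classes scores purity 1/3, ARI 0", {
  assignments <- stats::setNames(rep(0L, 12), paste0("s", 1:12))
  y <- tiny_labels(c("a", "b", "c"), 4)
  names(y) <- names(assignments)
  v <- align_and_score(assignments, y)
  expect_equal(v$purity, 1 / 3)
  expect_equal(v$ari, 0)
})

test_that("aligned accuracy equals the exhaustive bijection oracle; purity equals sum-of-max", {
  set.seed(44)
  for (rep in 1:25) {
    n <- 12
    assignments <- stats::setNames(sample(0:2, n, TRUE), paste0("s", 1:n))
    y <- factor(sample(c("x", "y", "z"), n, TRUE), levels = c("x", "y", "z"))
    names(y) <- names(assignments)
    if (length(unique(assignments)) < 3 || nlevels(droplevels(y)) < 3) next
    v <- align_and_score(assignments, y)
    conf <- table(assignments, as.character(y))
    best <- 0
    for (pm in ovaboost:::perm_all(3)) {
      best <- max(best, sum(conf[cbind(1:3, pm)]))
    }
    expect_equal(v$accuracy, best / n)
    expect_equal(v$purity, sum(apply(conf, 1, max)) / n)
  }
})

test_that("ARI ignores cluster labels and is 1 only for identical partitions", {
  assignments <- stats::setNames(c(0, 0, 1, 1, 2, 2), paste0("s", 1:6))
  y <- factor(c("b", "b", "c", "c", "a", "a")); names(y) <- names(assignments)
  v <- align_and_score(assignments, y)
  expect_equal(v$ari, 1)
  relabeled <- stats::setNames(c(2, 2, 0, 0, 1, 1), names(assignments))
  expect_equal(align_and_score(relabeled, y)$ari, 1)
})

test_that("substage grouping maps collapse labels before scoring", {
  assignments <- stats::setNames(rep(0:2, each = 5), paste0("s", 1:15))
  y <- factor(c(rep("OVT", 5), "OVC_IA", "OVC_IA", "OVC_IA", "OVC_IC", "OVC_IA",
                "OVC_IIIB", rep("OVC_IIIC", 4)))
  names(y) <- names(assignments)
  gm <- c(OVC_IA = "OVC_I", OVC_IC = "OVC_I",
          OVC_IIIB = "OVC_III", OVC_IIIC = "OVC_III")
  v <- align_and_score(assignments, y, group_map = gm)
  expect_equal(v$accuracy, 1)
  expect_identical(colnames(v$confusion), c("OVT", "OVC_I", "OVC_III"))
})

test_that("dendrograms export as readable newick with sample tips", {
  set.seed(45)
  X <- matrix(rnorm(4 * 9), 4, 9,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:9)))
  cl <- cluster_samples(X, 3, method = "agglomerative", seed = 1)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(cl$tree, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(X))
})
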