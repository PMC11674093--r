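#' Cluster samples on a selected gene panel
#'
#' Runs k-means (Euclidean, 10 restarts keeping the lowest within-cluster
#' sum of squares, seeded) or agglomerative hierarchical clustering
#' (chosen linkage on Euclidean distances, tree cut at K) on the samples
#' of a panel-restricted expression matrix. Genes are standardized first
#' by default. Cluster ids are relabeled 0..K-1 by order of first
#' appearance in sample order, so they are stable and comparable across
#' methods.
#'
#' @param X_sel panel-genes x samples matrix.
#' @param K number of clusters (typically the class count).
#' @param method `"kmeans"` or `"agglomerative"`.
#' @param linkage linkage for agglomerative clustering: `"ward"`
#'   (Ward's minimum variance, `ward.D2`), `"average"`, or `"complete"`.
#' @param seed RNG seed (k-means restarts).
#' @param standardize standardize genes before clustering (default TRUE).
#' @return list with `assignments` (named integer vector, clusters
#'   0..K-1), `method`, and for agglomerative clustering the `hclust`
#'   tree in `tree`.
#' @export
cluster_samples <- function(X_sel, K, method = c("kmeans", "agglomerative"),
                            linkage = c("ward", "average", "complete"),
                            seed = 1L, standardize = TRUE) {
  validate_expression(X_sel)
  method <- match.arg(method)
  linkage <- match.arg(linkage)
  K <- as.integer(K)
  if (K < 1L || K > ncol(X_sel)) stop_config("K must be in [1, %d]", ncol(X_sel))
  Z <- if (standardize) standardize_genes(X_sel) else X_sel
  obs <- t(Z)
  tree <- NULL
  if (method == "kmeans") {
    raw <- if (K == ncol(X_sel)) {
      stats::setNames(seq_len(K), rownames(obs))  # singleton clusters
    } else {
      with_seed(seed, stats::kmeans(obs, centers = K, nstart = 10L,
                                    iter.max = 100L))$cluster
    }
  } else {
    hc_method <- switch(linkage, ward = "ward.D2", average = "average",
                        complete = "complete")
    tree <- stats::hclust(stats::dist(obs), method = hc_method)
    raw <- stats::cutree(tree, k = K)
  }
  relabel <- stats::setNames(seq_along(unique(raw)) - 1L, unique(raw))
  assignments <- stats::setNames(as.integer(relabel[as.character(raw)]),
                                 rownames(obs))
  list(assignments = assignments, method = method, linkage = linkage,
       K = K, tree = tree)
}

#' Align clusters to classes and score the clustering
#'
#' Builds the clusters x classes contingency table and scores it three
#' ways: `purity` — the fraction of samples in their cluster's majority
#' class; `accuracy` — the matched fraction under the best cluster-to-
#' class mapping (the optimal bijection over class permutations when
#' K = C, the majority mapping otherwise), which is what a printed
#' cluster-vs-stage table measures; and the adjusted Rand index. An
#' optional label-grouping map (e.g. collapsing substages IA, IC into
#' stage I) is applied to the labels before scoring.
#'
#' @param assignments named integer cluster vector from
#'   [cluster_samples()] (or any clustering covering the labeled
#'   samples).
#' @param y named factor of class labels for exactly those samples.
#' @param group_map optional named character vector mapping original
#'   label -> grouped label.
#' @return a `cluster_verification`: `confusion` (K x C counts),
#'   `mapping` (cluster -> class), `purity`, `accuracy`, `ari`,
#'   `assignments`.
#' @export
align_and_score <- function(assignments, y, group_map = NULL) {
  if (!setequal(names(assignments), names(y))) {
    stop_config("assignments and labels cover different samples")
  }
  y <- y[names(assignments)]
  labs <- as.character(y)
  if (!is.null(group_map)) {
    hit <- labs %in% names(group_map)
    labs[hit] <- unname(group_map[labs[hit]])
  }
  labs <- factor(labs, levels = unique(labs))
  clusters <- sort(unique(assignments))
  confusion <- table(cluster = factor(assignments, levels = clusters),
                     class = labs)
  n <- sum(confusion)
  purity <- sum(apply(confusion, 1L, max)) / n

  K <- nrow(confusion); C <- ncol(confusion)
  if (K == C && K <= 8L) {
    perms <- perm_all(C)
    matched <- vapply(perms, function(pm) {
      sum(confusion[cbind(seq_len(K), pm)])
    }, numeric(1))
    best <- perms[[which.max(matched)]]
    mapping <- stats::setNames(colnames(confusion)[best], rownames(confusion))
    accuracy <- max(matched) / n
  } else {
    mapping <- stats::setNames(colnames(confusion)[apply(confusion, 1L, which.max)],
                               rownames(confusion))
    accuracy <- sum(apply(confusion, 1L, max)) / n
  }
  ari <- mclust::adjustedRandIndex(assignments, labs)
  structure(list(confusion = unclass(confusion), mapping = mapping,
                 purity = purity, accuracy = accuracy, ari = ari,
                 assignments = assignments),
            class = "cluster_verification")
}

# all permutations of 1..n (n <= 8)
perm_all <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (pm in perm_all(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[pm])
    }
  }
  out
}

#' @export
print.cluster_verification <- function(x, ...) {
  cat(sprintf("cluster_verification: purity %.3f, aligned accuracy %.3f, ARI %.3f\n",
              x$purity, x$accuracy, x$ari))
  print(x$confusion)
  invisible(x)
}

#' Export an agglomerative-clustering dendrogram as newick
#'
#' @param tree an `hclust` object (from [cluster_samples()] with
#'   `method = "agglomerative"`).
#' @param path output newick file.
#' @export
write_dendrogram <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
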