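#' Recursive feature elimination with a boosted learner
#'
#' Iteratively fits the learner on the surviving genes, scores every
#' survivor under the learner's importance criterion, and removes the
#' `ceiling(step_fraction * surviving)` lowest-importance genes (at least
#' one per iteration, never dropping below `target_size`; the final
#' iteration removes exactly enough to land on `target_size`). Survivors
#' are returned ordered by final-model importance; ties are broken by the
#' previous iteration's importance, then by gene id.
#'
#' @param X genes x samples expression matrix.
#' @param y class labels aligned to `colnames(X)`.
#' @param learner a [learner_spec()].
#' @param target_size number of genes to retain.
#' @param step_fraction fraction of surviving genes removed per iteration,
#'   in (0, 1).
#' @return a `ranked_feature_set`: `gene_ids` (most to least important),
#'   `scores` (final-model importance), `elimination_trace` (list of
#'   removed gene ids per iteration), `learner`.
#' @export
rfe_rank <- function(X, y, learner, target_size = 30L, step_fraction = 0.1) {
  validate_expression(X)
  y <- align_labels(X, y)
  if (nlevels(droplevels(y)) < 2L) stop_config("rfe_rank needs >= 2 classes")
  p <- nrow(X)
  target_size <- as.integer(target_size)
  if (target_size < 1L || target_size > p) {
    stop_config("target_size must be in [1, %d], got %d", p, target_size)
  }
  if (step_fraction <= 0 || step_fraction >= 1) stop_config("step_fraction must be in (0, 1)")

  surviving <- rownames(X)
  prev_imp <- stats::setNames(rep(0, p), surviving)
  # Elimination ties (typically blocks of zero-importance genes) are broken
  # by a learner-seed-derived random key rather than gene id: a fixed
  # lexicographic rule would make every learner retain the *same* block of
  # never-used genes, which a downstream consensus vote would mistake for
  # multi-learner agreement. Deterministic given the learner seed.
  tie_key <- with_seed(derive_seed(learner$seed, 7L),
                       stats::setNames(sample.int(p), surviving))
  trace <- list()
  iter <- 0L
  repeat {
    fit <- fit_learner(learner, t(X[surviving, , drop = FALSE]), y)
    imp <- learner_importance(fit, t(X[surviving, , drop = FALSE]), y)
    if (length(surviving) == target_size) break
    iter <- iter + 1L
    n_drop <- min(max(1L, ceiling(step_fraction * length(surviving))),
                  length(surviving) - target_size)
    # ascending importance; ties: previous-iteration importance, then the
    # seeded random key
    ord <- order(imp[surviving], prev_imp[surviving], tie_key[surviving])
    drop <- surviving[ord][seq_len(n_drop)]
    trace[[iter]] <- drop
    prev_imp[surviving] <- imp[surviving]
    surviving <- setdiff(surviving, drop)
  }
  ord <- order(-imp[surviving], -prev_imp[surviving], surviving)
  kept <- surviving[ord]
  structure(list(learner = learner,
                 gene_ids = kept,
                 scores = imp[kept],
                 elimination_trace = trace,
                 target_size = target_size),
            class = "ranked_feature_set")
}

#' Per-gene one-way ANOVA F scores
#'
#' For each gene, F = (between-class SS / (g - 1)) / (within-class SS /
#' (n - g)) across the label groups. A constant gene (both sums of squares
#' zero) is flagged degenerate with F = 0; a gene constant within every
#' class but differing between classes has infinite F.
#'
#' @param X genes x samples matrix.
#' @param y class labels aligned to `colnames(X)`.
#' @return list with `f` (named numeric vector, one F per gene) and
#'   `degenerate` (named logical vector).
#' @export
anova_f <- function(X, y) {
  validate_expression(X)
  y <- align_labels(X, y)
  y <- droplevels(y)
  g <- nlevels(y); n <- length(y)
  if (g < 2L) stop_config("anova_f needs >= 2 classes")
  if (any(table(y) < 2L)) stop_config("every class needs >= 2 samples for ANOVA")
  grand <- rowMeans(X)
  sst <- rowSums((X - grand)^2)
  ssb <- numeric(nrow(X))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    ssb <- ssb + length(idx) * (rowMeans(X[, idx, drop = FALSE]) - grand)^2
  }
  ssw <- sst - ssb
  ssw[ssw < 0] <- 0  # guard tiny negative rounding
  degenerate <- ssb <= .Machine$double.eps * pmax(1, abs(grand))^2 & ssw <= .Machine$double.eps
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[ssw == 0 & ssb > 0] <- Inf
  f[degenerate] <- 0
  names(f) <- rownames(X)
  names(degenerate) <- rownames(X)
  list(f = f, degenerate = degenerate)
}

#' Correlation of selected genes with each other and the class label
#'
#' Pearson correlation matrix over the selected genes (as sample vectors)
#' plus a numeric-coded label column. The default coding assigns 0, 1, 2,
#' ... along the class order, i.e. the progression direction of the
#' classes. Zero-variance genes get NA correlations (flagged, never a
#' silent 0) with a unit diagonal.
#'
#' @param X_sel selected-genes x samples matrix.
#' @param y class labels aligned to `colnames(X_sel)`.
#' @param coding named numeric vector mapping class to number; default
#'   `0:(K-1)` along the class order.
#' @return symmetric (s+1) x (s+1) correlation matrix; the last
#'   row/column is named `"label"`.
#' @export
correlation_with_label <- function(X_sel, y, coding = NULL) {
  validate_expression(X_sel)
  y <- align_labels(X_sel, y)
  if (is.null(coding)) {
    coding <- stats::setNames(seq_len(nlevels(y)) - 1, levels(y))
  }
  if (anyDuplicated(coding)) stop_config("label coding must assign distinct numbers")
  coded <- as.numeric(coding[as.character(y)])
  M <- rbind(X_sel, label = coded)
  sds <- apply(M, 1L, stats::sd)
  R <- suppressWarnings(stats::cor(t(M)))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  R
}
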