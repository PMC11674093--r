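#' Cross-validation configuration
#'
#' @param k number of folds (default 3).
#' @param learners list of [learner_spec()]s used for classification;
#'   defaults to the gbdt / catboost_like / xgboost_like trio.
#' @param augmentation a [gan_config()] to enable in-fold GAN
#'   augmentation, or `NULL` to disable it.
#' @param per_class_multiplier synthetic samples generated per real
#'   training sample of each class (default 10).
#' @param seed integer base seed; folds, learners and per-fold GANs all
#'   derive their own seeds from it.
#' @return a `cv_config` list.
#' @export
cv_config <- function(k = 3L, learners = NULL, augmentation = NULL,
                      per_class_multiplier = 10L, seed = 1L) {
  cfg <- list(k = as.integer(k),
              learners = learners %||% default_learners(seed),
              augmentation = augmentation,
              per_class_multiplier = as.integer(per_class_multiplier),
              seed = as.integer(seed))
  if (cfg$k < 2L) stop_config("k must be >= 2")
  if (!is.null(cfg$augmentation)) stopifnot(inherits(cfg$augmentation, "gan_config"))
  class(cfg) <- "cv_config"
  cfg
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members to folds
#' round-robin, with a class-dependent starting fold so remainders spread
#' evenly; per-fold class proportions stay within one sample of the
#' global proportions. Classes with fewer members than `k` still get
#' dealt round-robin, so every fold tests every class where possible.
#'
#' @param y named factor of class labels.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return named integer vector mapping sample id to fold in `1:k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop_config("k must be >= 2")
  if (k > length(y)) stop_config("k (%d) exceeds sample count (%d)", k, length(y))
  y <- droplevels(y)
  folds <- stats::setNames(integer(length(y)), names(y))
  with_seed(seed, {
    assigned <- 0L   # rotating pointer so class remainders spread over folds
    for (ci in seq_len(nlevels(y))) {
      ids <- names(y)[y == levels(y)[ci]]
      ids <- ids[sample.int(length(ids))]
      folds[ids] <- ((seq_along(ids) - 1L + assigned) %% k) + 1L
      assigned <- assigned + length(ids)
    }
  })
  folds
}

#' Soft-voting ensemble prediction
#'
#' Averages class-probability vectors across fitted learners and takes
#' the argmax; exact ties resolve to the earliest class in the class
#' order. Each learner's probability rows must sum to 1 within 1e-6.
#'
#' @param fits list of fitted learners (internal objects produced inside
#'   [run_cv()]).
#' @param X_obs samples x panel-genes matrix to predict.
#' @return list with `classes` (factor in class order) and `probs`
#'   (n x K mean-probability matrix).
#' @export
ensemble_predict <- function(fits, X_obs) {
  stopifnot(length(fits) >= 1L)
  soft_vote(lapply(fits, predict_learner, X_obs = X_obs))
}

# Mean of class-probability matrices, argmax with first-in-class-order
# tie-break (which.max takes the first maximum; columns are in class
# order).
soft_vote <- function(probs) {
  for (P in probs) {
    if (any(abs(rowSums(P) - 1) > 1e-6)) {
      stop_config("learner probability rows do not sum to 1")
    }
  }
  mean_p <- Reduce(`+`, probs) / length(probs)
  cls <- factor(colnames(mean_p)[apply(mean_p, 1L, which.max)],
                levels = colnames(mean_p))
  list(classes = cls, probs = mean_p)
}

#' Leakage-safe k-fold cross-validation of a gene panel
#'
#' For each fold: the expression matrix is restricted to the panel genes;
#' if augmentation is enabled, a class-conditional GAN is trained from
#' scratch on the training fold only (fold-specific seed) and synthetic
#' samples — `per_class_multiplier` per real training sample of each
#' class — are appended to the training fold; every learner is fitted on
#' the (augmented) training fold; the held-out fold is predicted by soft
#' voting. Test folds contain original samples only: a synthetic sample
#' id intersecting a test fold is a hard assertion failure, and the
#' report is checked to contain exactly one prediction per original
#' sample.
#'
#' @param X genes x samples expression matrix.
#' @param y class labels aligned to `colnames(X)`.
#' @param panel character vector of panel gene ids, or a
#'   `consensus_selection`.
#' @param cfg a [cv_config()].
#' @return a `cv_report`: `fold_assignments`, `per_fold` (n_test,
#'   n_correct, accuracy), `overall_accuracy` (percent),
#'   `overall_fraction` (n_correct / n as a string), `per_class_recall`,
#'   `predictions` (sample_id, fold, true, predicted), `config_echo`.
#' @export
run_cv <- function(X, y, panel, cfg = cv_config()) {
  validate_expression(X)
  y <- align_labels(X, y)
  if (inherits(panel, "consensus_selection")) panel <- panel$gene_id
  panel <- as.character(panel)
  if (!all(panel %in% rownames(X))) {
    stop_config("panel gene(s) missing from the expression matrix: %s",
                paste(setdiff(panel, rownames(X)), collapse = ", "))
  }
  Xp <- X[panel, , drop = FALSE]
  folds <- stratified_folds(y, cfg$k, seed = derive_seed(cfg$seed, 0L))
  n <- length(y)

  preds <- data.frame(sample_id = character(0), fold = integer(0),
                      true = character(0), predicted = character(0),
                      stringsAsFactors = FALSE)
  per_fold <- data.frame(fold = seq_len(cfg$k), n_test = 0L, n_correct = 0L,
                         accuracy = NA_real_)
  for (f in seq_len(cfg$k)) {
    test_ids <- names(folds)[folds == f]
    train_ids <- setdiff(names(folds), test_ids)
    X_train <- Xp[, train_ids, drop = FALSE]
    y_train <- droplevels(y[train_ids])
    origin <- stats::setNames(rep("real", length(train_ids)), train_ids)

    if (!is.null(cfg$augmentation) && cfg$per_class_multiplier > 0L) {
      gcfg <- cfg$augmentation
      gcfg$seed <- derive_seed(cfg$seed, f)
      model <- train_gan(X_train, y_train, gcfg)
      for (cl in levels(y_train)) {
        n_real <- sum(y_train == cl)
        n_syn <- n_real * cfg$per_class_multiplier
        S <- generate_samples(model, cl, n_syn,
                              seed = derive_seed(gcfg$seed, match(cl, levels(y_train))))
        if (nrow(S) > 0L) {
          syn_ids <- sprintf("%s_f%d", rownames(S), f)
          rownames(S) <- syn_ids
          X_train <- cbind(X_train, t(S))
          y_train <- factor(c(as.character(y_train), rep(cl, nrow(S))),
                            levels = levels(y_train))
          names(y_train) <- colnames(X_train)
          origin[syn_ids] <- "synthetic"
        }
      }
    }
    # leakage assertion: no synthetic-origin id may reach the test fold
    leaked <- intersect(names(origin)[origin == "synthetic"], test_ids)
    if (length(leaked) > 0L) {
      stop(sprintf("LEAKAGE: synthetic sample(s) in test fold %d: %s",
                   f, paste(leaked, collapse = ", ")), call. = FALSE)
    }

    fits <- lapply(cfg$learners, fit_learner, X_obs = t(X_train), y = y_train)
    pr <- ensemble_predict(fits, t(Xp[, test_ids, drop = FALSE]))
    correct <- as.character(pr$classes) == as.character(y[test_ids])
    per_fold$n_test[f] <- length(test_ids)
    per_fold$n_correct[f] <- sum(correct)
    per_fold$accuracy[f] <- mean(correct)
    preds <- rbind(preds, data.frame(sample_id = test_ids, fold = f,
                                     true = as.character(y[test_ids]),
                                     predicted = as.character(pr$classes),
                                     stringsAsFactors = FALSE))
  }
  stopifnot(sum(per_fold$n_test) == n,
            !anyDuplicated(preds$sample_id),
            all(preds$sample_id %in% names(y)))

  recall <- vapply(levels(y), function(cl) {
    rows <- preds$true == cl
    if (!any(rows)) NA_real_ else mean(preds$predicted[rows] == cl)
  }, numeric(1))
  rep <- list(fold_assignments = as.list(folds),
              per_fold = per_fold,
              overall_accuracy = 100 * sum(per_fold$n_correct) / n,
              overall_fraction = sprintf("%d/%d", sum(per_fold$n_correct), n),
              per_class_recall = as.list(recall),
              predictions = preds,
              config_echo = list(
                k = cfg$k, seed = cfg$seed,
                per_class_multiplier = cfg$per_class_multiplier,
                augmentation = if (is.null(cfg$augmentation)) NULL else unclass(cfg$augmentation),
                learners = lapply(cfg$learners, unclass),
                panel = panel))
  class(rep) <- "cv_report"
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: pooled accuracy %.2f%% (%s) over %d folds\n",
              x$overall_accuracy, x$overall_fraction, nrow(x$per_fold)))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}
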