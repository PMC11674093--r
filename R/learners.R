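#' Specify a boosted learner and its feature-importance criterion
#'
#' The selection ensemble uses three gradient-boosted learners that differ
#' by the importance criterion driving their recursive feature
#' elimination: `gbdt` ranks by *weight* (how often a feature is split
#' on), `catboost_like` by *prediction value change* (how much predicted
#' class probabilities move when the feature's values are permuted), and
#' `xgboost_like` by *gain* (total loss reduction contributed by the
#' feature's splits). All three are served by one gradient-boosted tree
#' backend; a learner kind is defined by its criterion, not by a vendor
#' implementation. The boosted model itself — an additive ensemble of `m`
#' trees fit by gradient boosting — is the documented contract of the
#' backend and is not reimplemented here.
#'
#' @param kind one of `"gbdt"`, `"catboost_like"`, `"xgboost_like"`.
#' @param trees number of boosting rounds.
#' @param depth maximum tree depth.
#' @param learning_rate shrinkage per round.
#' @param colsample fraction of features sampled per tree. Sub-unit
#'   column sampling decorrelates trees and spreads importance across
#'   redundant discriminative genes, so recursive elimination does not
#'   discard genes merely shadowed by a correlated partner.
#' @param seed integer seed for the backend and for permutation
#'   importance.
#' @return a `learner_spec` list with the criterion fixed by `kind`.
#' @export
learner_spec <- function(kind = c("gbdt", "catboost_like", "xgboost_like"),
                         trees = 200L, depth = 3L, learning_rate = 0.1,
                         colsample = 0.3, seed = 1L) {
  kind <- match.arg(kind)
  criterion <- switch(kind,
    gbdt = "weight",
    catboost_like = "prediction_value_change",
    xgboost_like = "gain")
  structure(list(kind = kind, importance_criterion = criterion,
                 trees = as.integer(trees), depth = as.integer(depth),
                 learning_rate = as.numeric(learning_rate),
                 colsample = as.numeric(colsample),
                 seed = as.integer(seed)),
            class = "learner_spec")
}

#' Default learner trio for ensemble selection and classification
#'
#' @param seed base seed; each learner gets a distinct derived seed.
#' @return list of three [learner_spec()]s.
#' @export
default_learners <- function(seed = 1L) {
  kinds <- c("gbdt", "catboost_like", "xgboost_like")
  lapply(seq_along(kinds), function(i) {
    learner_spec(kinds[i], seed = derive_seed(seed, i))
  })
}

# Fit the boosted backend on samples x genes data. y is a factor whose
# levels define the class order used everywhere downstream.
fit_learner <- function(spec, X_obs, y) {
  stopifnot(inherits(spec, "learner_spec"), is.matrix(X_obs), is.factor(y))
  if (nlevels(droplevels(y)) < 2L) stop_config("need >= 2 classes to fit a classifier")
  K <- nlevels(y)
  d <- xgboost::xgb.DMatrix(X_obs, label = as.integer(y) - 1L, nthread = 1)
  params <- list(objective = "multi:softprob", num_class = K,
                 max_depth = spec$depth, eta = spec$learning_rate,
                 colsample_bytree = spec$colsample,
                 nthread = 1, seed = spec$seed)
  booster <- xgboost::xgb.train(params = params, data = d,
                                nrounds = spec$trees, verbose = 0)
  structure(list(booster = booster, spec = spec,
                 features = colnames(X_obs), classes = levels(y)),
            class = "fitted_learner")
}

# Class-probability predictions (n x K, columns in class order).
predict_learner <- function(fit, X_obs) {
  stopifnot(inherits(fit, "fitted_learner"))
  X_obs <- X_obs[, fit$features, drop = FALSE]
  P <- predict(fit$booster, xgboost::xgb.DMatrix(X_obs, nthread = 1))
  P <- matrix(P, nrow = nrow(X_obs), byrow = FALSE,
              dimnames = list(rownames(X_obs), fit$classes))
  P
}

# Importance of every feature under the spec's criterion. Features never
# used by any tree get importance 0 (they contributed nothing).
learner_importance <- function(fit, X_obs, y = NULL) {
  spec <- fit$spec
  feats <- fit$features
  out <- stats::setNames(numeric(length(feats)), feats)
  if (spec$importance_criterion %in% c("weight", "gain")) {
    imp <- xgboost::xgb.importance(model = fit$booster)
    col <- if (spec$importance_criterion == "gain") "Gain" else "Frequency"
    if (!is.null(imp) && nrow(imp) > 0L) {
      out[imp$Feature] <- imp[[col]]
    }
    return(out)
  }
  # prediction_value_change: mean absolute change of predicted class
  # probabilities when one feature's column is permuted (seeded).
  base <- predict_learner(fit, X_obs)
  with_seed(derive_seed(spec$seed, 104729L), {
    perm <- sample.int(nrow(X_obs))
    for (j in seq_along(feats)) {
      Xp <- X_obs
      Xp[, j] <- Xp[perm, j]
      out[j] <- mean(abs(predict_learner(fit, Xp) - base))
    }
  })
  out
}
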