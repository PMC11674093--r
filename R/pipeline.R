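#' Run the three-learner ensemble selection
#'
#' Runs recursive feature elimination to `target_size` genes under each
#' learner's importance criterion, then the 2-of-3 consensus vote down to
#' `final_size` genes.
#'
#' @param X genes x samples expression matrix.
#' @param y class labels aligned to `colnames(X)`.
#' @param target_size per-learner subset size (default 30).
#' @param final_size consensus panel size (default 10).
#' @param step_fraction RFE elimination fraction per iteration.
#' @param vote_min minimum votes for a consensus candidate.
#' @param seed base seed for the learner trio.
#' @return list with `selection` (a `consensus_selection`) and `subsets`
#'   (the three `ranked_feature_set`s).
#' @export
select_panel <- function(X, y, target_size = 30L, final_size = 10L,
                         step_fraction = 0.1, vote_min = 2L, seed = 1L) {
  learners <- default_learners(seed)
  subsets <- lapply(learners, function(sp) {
    rfe_rank(X, y, sp, target_size = target_size, step_fraction = step_fraction)
  })
  sel <- consensus_select(subsets, vote_min = vote_min, final_size = final_size)
  list(selection = sel, subsets = subsets)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings. Defaults mirror the method's
#' headline configuration: 30-gene subsets per learner, a 10-gene
#' consensus panel, 3-fold stratified cross-validation with in-fold GAN
#' augmentation at 10 synthetic samples per real one, and K = class
#' count clustering verification.
#'
#' @param expression,labels input file paths (TSV/CSV), or `NULL` when
#'   the matrices are passed to [run_pipeline()] directly.
#' @param out_dir output directory for artifacts.
#' @param target_size,final_size,step_fraction,vote_min selection stage.
#' @param augmentation a [gan_config()] or `NULL` to disable.
#' @param per_class_multiplier synthetic-to-real ratio per class.
#' @param k cross-validation folds.
#' @param cluster_method,linkage,group_map clustering stage;
#'   `group_map` maps original labels to grouped labels before scoring.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, labels = NULL, out_dir = NULL,
                            target_size = 30L, final_size = 10L,
                            step_fraction = 0.1, vote_min = 2L,
                            augmentation = gan_config(),
                            per_class_multiplier = 10L, k = 3L,
                            cluster_method = "kmeans", linkage = "ward",
                            group_map = NULL, seed = 1L) {
  if (final_size > target_size) {
    stop_config("final_size (%d) > target_size (%d)", final_size, target_size)
  }
  cfg <- list(expression = expression, labels = labels, out_dir = out_dir,
              target_size = as.integer(target_size),
              final_size = as.integer(final_size),
              step_fraction = as.numeric(step_fraction),
              vote_min = as.integer(vote_min),
              augmentation = augmentation,
              per_class_multiplier = as.integer(per_class_multiplier),
              k = as.integer(k), cluster_method = cluster_method,
              linkage = linkage, group_map = group_map,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline: selection, augmented CV, clustering
#'
#' Executes the single-pass flow — ensemble RFE + consensus selection on
#' the full dataset, leakage-safe augmented cross-validation of the
#' selected panel, then unsupervised clustering verification — and, when
#' `cfg$out_dir` is set, writes every intermediate artifact (per-learner
#' subsets, selection TSV, F-score and correlation tables, CV report
#' JSON, cluster assignments and confusion, newick dendrogram, manifest
#' with config echo and seeds).
#'
#' @param cfg a [pipeline_config()].
#' @param X,y optional in-memory expression matrix and labels; read from
#'   `cfg$expression` / `cfg$labels` when omitted.
#' @return list with `selection`, `subsets`, `cv`, `kmeans`,
#'   `agglomerative`, `f_scores`, `correlations`.
#' @export
run_pipeline <- function(cfg, X = NULL, y = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(X)) X <- read_expression(cfg$expression)
  if (is.null(y)) y <- read_labels(cfg$labels)
  y <- align_labels(X, y)

  sel <- select_panel(X, y, target_size = cfg$target_size,
                      final_size = cfg$final_size,
                      step_fraction = cfg$step_fraction,
                      vote_min = cfg$vote_min, seed = cfg$seed)
  panel <- sel$selection$gene_id
  X_sel <- X[panel, , drop = FALSE]

  fs <- anova_f(X_sel, y)
  corr <- correlation_with_label(X_sel, y)

  cvc <- cv_config(k = cfg$k, learners = default_learners(cfg$seed),
                   augmentation = cfg$augmentation,
                   per_class_multiplier = cfg$per_class_multiplier,
                   seed = cfg$seed)
  cv <- run_cv(X, y, panel, cvc)

  K <- nlevels(droplevels(factor(
    if (is.null(cfg$group_map)) as.character(y) else {
      labs <- as.character(y)
      hit <- labs %in% names(cfg$group_map)
      labs[hit] <- unname(cfg$group_map[labs[hit]])
      labs
    })))
  km <- cluster_samples(X_sel, K, method = "kmeans",
                        seed = derive_seed(cfg$seed, 91L))
  ag <- cluster_samples(X_sel, K, method = "agglomerative",
                        linkage = cfg$linkage, seed = derive_seed(cfg$seed, 92L))
  km_v <- align_and_score(km$assignments, y, group_map = cfg$group_map)
  ag_v <- align_and_score(ag$assignments, y, group_map = cfg$group_map)

  out <- list(selection = sel$selection, subsets = sel$subsets, cv = cv,
              kmeans = km_v, agglomerative = ag_v,
              f_scores = fs, correlations = corr)
  if (!is.null(cfg$out_dir)) write_artifacts(out, ag$tree, cfg)
  out
}

write_artifacts <- function(res, tree, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(f) file.path(cfg$out_dir, f)
  write_selection(res$selection, op("selection.tsv"))
  for (s in res$subsets) {
    utils::write.table(
      data.frame(gene_id = s$gene_ids, importance = unname(s$scores)),
      op(sprintf("subset_%s.tsv", s$learner$kind)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(gene_id = names(res$f_scores$f), f_score = unname(res$f_scores$f),
               degenerate = unname(res$f_scores$degenerate)),
    op("f_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$correlations, op("correlations.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  write_report(res$cv, op("cv_report.json"))
  for (nm in c("kmeans", "agglomerative")) {
    v <- res[[nm]]
    utils::write.table(
      data.frame(sample_id = names(v$assignments), cluster = unname(v$assignments)),
      op(sprintf("clusters_%s.tsv", nm)), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(v$confusion, op(sprintf("confusion_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(tree)) write_dendrogram(tree, op("dendrogram.nwk"))
  cfg_echo <- lapply(unclass(cfg)[setdiff(names(cfg), c("expression", "labels"))],
                     function(x) if (is.object(x)) unclass(x) else x)
  manifest <- list(package = "ovaboost",
                   version = as.character(utils::packageVersion("ovaboost")),
                   seed = cfg$seed,
                   config = cfg_echo,
                   metrics = list(
                     overall_accuracy = res$cv$overall_accuracy,
                     kmeans_purity = res$kmeans$purity,
                     kmeans_ari = res$kmeans$ari,
                     agglomerative_purity = res$agglomerative$purity,
                     agglomerative_ari = res$agglomerative$ari))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(cfg$out_dir)
}
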