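#' Configuration for the synthetic microarray generator
#'
#' Defaults emulate the target study design: thousands of mostly
#' uninformative genes, three classes (benign tumor, stage I cancer,
#' stage III cancer), five samples per class, and a small planted set of
#' class-discriminative genes whose means progress monotonically across
#' the class order.
#'
#' @param p total gene count.
#' @param classes class labels, in the order used for mean progression.
#' @param n_per_class samples per class.
#' @param n_informative number of planted discriminative genes.
#' @param effect class-to-class mean separation of informative genes, in
#'   units of the within-class standard deviation.
#' @param block_size size of consecutive-gene correlation blocks.
#' @param block_rho within-block (equicorrelated) correlation, in [0, 1).
#' @param noise_sd within-class standard deviation.
#' @param seed integer RNG seed; the dataset is a pure function of the
#'   config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(p = 9600L,
                       classes = c("OVT", "OVC_I", "OVC_III"),
                       n_per_class = 5L,
                       n_informative = 20L,
                       effect = 3,
                       block_size = 10L,
                       block_rho = 0.3,
                       noise_sd = 1,
                       seed = 1L) {
  cfg <- list(p = as.integer(p), classes = as.character(classes),
              n_per_class = as.integer(n_per_class),
              n_informative = as.integer(n_informative),
              effect = as.numeric(effect), block_size = as.integer(block_size),
              block_rho = as.numeric(block_rho), noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  if (cfg$n_informative > cfg$p) stop_config("n_informative (%d) > p (%d)", cfg$n_informative, cfg$p)
  if (cfg$effect < 0) stop_config("effect must be >= 0")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) stop_config("block_rho must be in [0, 1)")
  if (length(cfg$classes) < 2L) stop_config("need >= 2 classes")
  if (cfg$block_size < 1L) stop_config("block_size must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a microarray-like dataset with known ground truth
#'
#' Generates a genes x samples matrix of continuous (log-intensity-like)
#' values. Genes are partitioned into consecutive equicorrelated blocks of
#' `block_size` with correlation `block_rho`; each gene has its own
#' baseline level. Informative genes are placed at evenly spaced positions
#' (so they land in distinct blocks whenever possible) and receive
#' class-specific mean shifts evenly spaced by `effect * noise_sd` along
#' the class order — a stage-progression-like signal. Uninformative genes
#' share one mean across classes.
#'
#' @param cfg a [sim_config()].
#' @return a `simulated_dataset` list: `matrix` (genes x samples),
#'   `labels` (named factor), `truth` (character vector of planted
#'   informative gene ids).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$p; K <- length(cfg$classes); n <- cfg$n_per_class * K
  gene_ids <- sprintf("g%05d", seq_len(p))
  sample_ids <- unlist(lapply(seq_len(K), function(k) {
    sprintf("%s_s%02d", cfg$classes[k], seq_len(cfg$n_per_class))
  }))
  labels <- factor(rep(cfg$classes, each = cfg$n_per_class), levels = cfg$classes)
  names(labels) <- sample_ids

  informative_idx <- if (cfg$n_informative > 0L) {
    unique(round(seq(1L, p, length.out = cfg$n_informative)))
  } else integer(0)
  # rounding can collide at tiny p; backfill to keep exactly n_informative
  if (length(informative_idx) < cfg$n_informative) {
    pool <- setdiff(seq_len(p), informative_idx)
    informative_idx <- sort(c(informative_idx,
                              pool[seq_len(cfg$n_informative - length(informative_idx))]))
  }

  block_of <- (seq_len(p) - 1L) %/% cfg$block_size
  n_blocks <- max(block_of) + 1L

  with_seed(cfg$seed, {
    baseline <- stats::rnorm(p, mean = 7, sd = 1)
    # equicorrelated noise: x_g = sqrt(rho) * u_block + sqrt(1-rho) * e_g
    shared <- matrix(stats::rnorm(n_blocks * n), n_blocks, n)
    indep <- matrix(stats::rnorm(p * n), p, n)
    noise <- sqrt(cfg$block_rho) * shared[block_of + 1L, , drop = FALSE] +
      sqrt(1 - cfg$block_rho) * indep
    X <- baseline + cfg$noise_sd * noise
    if (length(informative_idx) > 0L && cfg$effect > 0) {
      class_idx <- as.integer(labels) - 1L           # 0 .. K-1 along class_order
      centered <- class_idx - (K - 1) / 2            # keep baseline the grand mean
      shift <- outer(rep(cfg$effect * cfg$noise_sd, length(informative_idx)), centered)
      X[informative_idx, ] <- X[informative_idx, ] + shift
    }
    dimnames(X) <- list(gene_ids, sample_ids)
    out <- list(matrix = X, labels = labels,
                truth = gene_ids[informative_idx], config = cfg)
    class(out) <- "simulated_dataset"
    out
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d genes x %d samples, %d classes, %d planted informative genes\n",
              nrow(x$matrix), ncol(x$matrix), nlevels(x$labels), length(x$truth)))
  invisible(x)
}
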