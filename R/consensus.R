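#' Consensus gene selection by 2-of-3 voting and rank aggregation
#'
#' Combines the ranked subsets produced by several learners' recursive
#' feature elimination into one panel. A gene is a candidate only if it
#' appears in at least `vote_min` subsets — genes championed by a single
#' learner are never used to pad a short panel. Candidates are ordered by
#' vote count (descending), then by mean normalized rank across the
#' subsets containing them (ascending; the rank of the gene at 1-based
#' position r in a subset of size m is (r-1)/(m-1), and 0 when m = 1),
#' then by gene id. Normalized ranks make the heterogeneous importance
#' scales of the learners (weight, prediction value change, gain)
#' comparable without comparing raw scores.
#'
#' @param subsets list of `ranked_feature_set`s over the same gene
#'   universe (typically 3).
#' @param vote_min minimum number of subsets a gene must appear in
#'   (default 2).
#' @param final_size panel size (default 10). If fewer candidates reach
#'   `vote_min`, the short panel is returned with a warning and
#'   `short = TRUE`.
#' @return a `consensus_selection`: data-frame-like with `gene_id`,
#'   `votes`, `aggregate_rank`, `rank`, plus attributes `source_ranks`
#'   (gene x learner 1-based ranks, NA where absent) and `short`.
#' @export
consensus_select <- function(subsets, vote_min = 2L, final_size = 10L) {
  stopifnot(length(subsets) >= 1L,
            all(vapply(subsets, inherits, logical(1), "ranked_feature_set")))
  vote_min <- as.integer(vote_min); final_size <- as.integer(final_size)
  if (vote_min < 1L || vote_min > length(subsets)) {
    stop_config("vote_min must be in [1, %d]", length(subsets))
  }
  if (final_size < 1L) stop_config("final_size must be >= 1")

  all_genes <- sort(unique(unlist(lapply(subsets, `[[`, "gene_ids"))))
  nsub <- length(subsets)
  src <- matrix(NA_integer_, length(all_genes), nsub,
                dimnames = list(all_genes,
                                vapply(subsets, function(s) s$learner$kind, character(1))))
  norm_rank <- matrix(NA_real_, length(all_genes), nsub, dimnames = dimnames(src))
  for (j in seq_len(nsub)) {
    ids <- subsets[[j]]$gene_ids
    m <- length(ids)
    src[ids, j] <- seq_len(m)
    norm_rank[ids, j] <- if (m == 1L) 0 else (seq_len(m) - 1) / (m - 1)
  }
  votes <- rowSums(!is.na(src))
  agg <- rowMeans(norm_rank, na.rm = TRUE)

  cand <- all_genes[votes >= vote_min]
  ord <- order(-votes[cand], agg[cand], cand)
  cand <- cand[ord]
  short <- length(cand) < final_size
  if (short) {
    warning(sprintf("only %d gene(s) reached %d votes; returning a short panel",
                    length(cand), vote_min), call. = FALSE)
  }
  panel <- utils::head(cand, final_size)
  out <- data.frame(gene_id = panel,
                    votes = as.integer(votes[panel]),
                    aggregate_rank = as.numeric(agg[panel]),
                    rank = seq_along(panel),
                    stringsAsFactors = FALSE)
  attr(out, "source_ranks") <- src[panel, , drop = FALSE]
  attr(out, "short") <- short
  attr(out, "vote_min") <- vote_min
  attr(out, "final_size") <- final_size
  class(out) <- c("consensus_selection", "data.frame")
  out
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf("consensus_selection: %d gene(s)%s\n", nrow(x),
              if (isTRUE(attr(x, "short"))) " [SHORT: candidate pool smaller than requested panel]" else ""))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
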