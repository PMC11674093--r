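# Fixture builders shared across test files. Everything is generated in
# code; no data files.

tiny_expression <- function() {
  matrix(c(1.5, 2.0,
           3.1, 4.2,
           5.0, 6.3),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
}

tiny_labels <- function(classes, per_class, prefix = "s") {
  y <- factor(rep(classes, each = per_class), levels = classes)
  names(y) <- sprintf("%s%02d", prefix, seq_along(y))
  y
}

# Ranked set wrapper so consensus can be tested without running RFE.
fake_ranked <- function(ids, kind = "gbdt") {
  structure(list(learner = learner_spec(kind),
                 gene_ids = ids,
                 scores = stats::setNames(rev(seq_along(ids)), ids),
                 elimination_trace = list(),
                 target_size = length(ids)),
            class = "ranked_feature_set")
}

# Brute-force consensus oracle: enumerate every gene's memberships.
consensus_oracle <- function(subsets, vote_min = 2L, final_size = 10L) {
  universe <- sort(unique(unlist(lapply(subsets, `[[`, "gene_ids"))))
  rows <- lapply(universe, function(g) {
    votes <- 0L; nr <- c()
    for (s in subsets) {
      r <- match(g, s$gene_ids)
      if (!is.na(r)) {
        votes <- votes + 1L
        m <- length(s$gene_ids)
        nr <- c(nr, if (m == 1L) 0 else (r - 1) / (m - 1))
      }
    }
    data.frame(gene_id = g, votes = votes,
               aggregate_rank = if (votes > 0) mean(nr) else NA_real_)
  })
  df <- do.call(rbind, rows)
  df <- df[df$votes >= vote_min, , drop = FALSE]
  df <- df[order(-df$votes, df$aggregate_rank, df$gene_id), , drop = FALSE]
  utils::head(df$gene_id, final_size)
}

# Two-pass sums-of-squares ANOVA oracle, one gene at a time.
anova_oracle <- function(x, y) {
  groups <- split(x, y)
  n <- length(x); g <- length(groups)
  grand <- mean(x)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (ssb == 0 && ssw == 0) return(0)
  (ssb / (g - 1)) / (ssw / (n - g))
}
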