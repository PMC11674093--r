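# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene-wise standardization
#'
#' Centers and scales each gene (row) to zero mean and unit variance across
#' samples. Zero-variance genes are centered only (scale left at 1) and
#' reported via the `degenerate` attribute.
#'
#' @param X numeric genes x samples matrix.
#' @return matrix of the same shape with attributes `center`, `scale`
#'   (per-gene) and `degenerate` (logical per gene).
#' @export
standardize_genes <- function(X) {
  stopifnot(is.matrix(X), is.numeric(X))
  ctr <- rowMeans(X)
  scl <- apply(X, 1L, stats::sd)
  degen <- !is.finite(scl) | scl == 0
  scl[degen] <- 1
  Z <- (X - ctr) / scl
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- scl
  attr(Z, "degenerate") <- degen
  Z
}

# Run code with a local, restored RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a bounded child seed from a base seed and an offset; keeps every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647L)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
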