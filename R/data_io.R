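#' Read an expression matrix from delimited text
#'
#' Reads a gene-expression table into the canonical genes x samples
#' orientation. The first column holds row identifiers and the header row
#' holds column identifiers; the delimiter is inferred from the file
#' extension (`.tsv`/`.txt` tab, `.csv` comma). Orientation is always
#' explicit — the reader never guesses whether rows are genes or samples.
#'
#' @param path path to a TSV/CSV file.
#' @param orientation `"genes_as_rows"` (default) if rows are genes, or
#'   `"samples_as_rows"` if the table is transposed on disk.
#' @return a numeric genes x samples matrix with gene identifiers as
#'   rownames and sample identifiers as colnames.
#' @export
read_expression <- function(path,
                            orientation = c("genes_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_config("expression file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop_config("empty or malformed expression table: %s", path)
  }
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  if (anyDuplicated(row_ids)) {
    stop_config("duplicate row identifiers in %s: %s", path,
                paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    stop_config("duplicate column identifiers in %s: %s", path,
                paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_config("non-numeric or non-finite cell at row '%s', column '%s' in %s",
                row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]], path)
  }
  dimnames(num) <- list(row_ids, col_ids)
  X <- if (orientation == "samples_as_rows") t(num) else num
  validate_expression(X)
  X
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate an expression matrix
#'
#' Checks the invariants every downstream module relies on: a numeric
#' matrix with unique, non-empty gene rownames and sample colnames, all
#' values finite, at least one gene and two samples.
#'
#' @param X candidate genes x samples matrix.
#' @return invisibly `X`; errors otherwise.
#' @export
validate_expression <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop_config("expression must be a numeric matrix")
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop_config("expression matrix needs gene rownames and sample colnames")
  }
  if (nrow(X) < 1L || ncol(X) < 2L) stop_config("need >= 1 gene and >= 2 samples")
  if (anyDuplicated(rownames(X))) stop_config("duplicate gene identifiers")
  if (anyDuplicated(colnames(X))) stop_config("duplicate sample identifiers")
  if (!all(is.finite(X))) stop_config("expression contains missing or non-finite values")
  invisible(X)
}

#' Read a sample-label table
#'
#' Two-column table (sample_id, label) with a header. Class order is fixed
#' to first-appearance order, which downstream code uses for numeric label
#' coding and deterministic tie-breaking.
#'
#' @param path path to a two-column TSV/CSV.
#' @return a factor of class labels, named by sample id, with levels in
#'   first-appearance order.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_config("label file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L || nrow(df) == 0L) stop_config("label table needs two columns and >= 1 row")
  ids <- df[[1L]]; labs <- df[[2L]]
  if (anyDuplicated(ids)) {
    stop_config("sample listed twice in %s: %s", path,
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(labs) | is.na(labs))) {
    stop_config("empty label for sample '%s'", ids[which(!nzchar(labs) | is.na(labs))[1L]])
  }
  y <- factor(labs, levels = unique(labs))
  names(y) <- ids
  y
}

#' Align a label vector to an expression matrix
#'
#' @param X genes x samples matrix.
#' @param y named factor from [read_labels()].
#' @return `y` reordered to `colnames(X)`; errors if any sample is missing
#'   from either side.
#' @export
align_labels <- function(X, y) {
  validate_expression(X)
  missing_in_y <- setdiff(colnames(X), names(y))
  missing_in_x <- setdiff(names(y), colnames(X))
  if (length(missing_in_y) || length(missing_in_x)) {
    stop_config("sample ids do not align: %s",
                paste(c(missing_in_y, missing_in_x), collapse = ", "))
  }
  y[colnames(X)]
}

#' Write an expression matrix / label vector to TSV
#'
#' @param X genes x samples matrix.
#' @param y named factor of labels.
#' @param path output file.
#' @return invisibly the path.
#' @rdname write_expression
#' @export
write_expression <- function(X, path) {
  validate_expression(X)
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_labels <- function(y, path) {
  df <- data.frame(sample_id = names(y), label = as.character(y))
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a consensus selection as TSV
#'
#' Columns: gene_id, votes, aggregate_rank, rank. An empty selection
#' produces a header-only file.
#'
#' @param sel a `consensus_selection` (see [consensus_select()]).
#' @param path output TSV path.
#' @return invisibly the path ([write_selection()]) or a data.frame
#'   ([read_selection()]).
#' @export
write_selection <- function(sel, path) {
  df <- as.data.frame(sel)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = c(gene_id = "character"))
}

#' Write / read a cross-validation report as JSON
#'
#' Serializes every field of a `cv_report` (fold assignments, per-fold and
#' pooled metrics, per-sample predictions, config echo, seeds) so that a
#' read-back reproduces the metrics bit-identically.
#'
#' @param rep a `cv_report` from [run_cv()].
#' @param path output JSON path.
#' @export
write_report <- function(rep, path) {
  # digits = I(17): full double precision so metrics survive a read-back
  # bit-identically
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
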