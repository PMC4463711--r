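#' Per-pair expression-ratio matrix
#'
#' Container for the central data structure of the pipeline: a pairs x genes
#' matrix of case/control intensity ratios (Cy5 case over Cy3 control within
#' each matched pair), together with gene annotations and pair identifiers.
#' All ratios are strictly positive; cells that could not be measured (e.g.
#' every spot of a gene flagged bad on one array) are explicit \code{NA}s,
#' never silent zeros.
#'
#' @param values numeric matrix, pairs in rows, genes in columns; entries
#'   positive and finite, or \code{NA} for missing cells.
#' @param genes data.frame of per-gene annotations with at least columns
#'   \code{symbol} and \code{public_id}; one row per matrix column. If
#'   \code{NULL}, built from the column names.
#' @param pair_ids character vector of pair identifiers (one per row).
#' @return An object of class \code{ratio_matrix}.
#' @export
ratio_matrix <- function(values, genes = NULL, pair_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  bad <- !is.na(values) & (values <= 0 | !is.finite(values))
  if (any(bad))
    stop("ratio values must be positive and finite (use NA for missing cells)")
  if (is.null(pair_ids)) {
    pair_ids <- rownames(values)
    if (is.null(pair_ids)) pair_ids <- sprintf("pair%03d", seq_len(nrow(values)))
  }
  if (length(pair_ids) != nrow(values))
    stop("`pair_ids` must have one entry per row of `values`")
  if (is.null(genes)) {
    sym <- colnames(values)
    if (is.null(sym)) sym <- sprintf("G%03d", seq_len(ncol(values)))
    genes <- data.frame(symbol = sym, public_id = NA_character_,
                        stringsAsFactors = FALSE)
  }
  if (nrow(genes) != ncol(values))
    stop("`genes` must have one row per column of `values`")
  if (anyDuplicated(genes$symbol))
    stop("gene symbols must be unique")
  dimnames(values) <- list(pair_ids, genes$symbol)
  structure(list(values = values, genes = genes, pair_ids = pair_ids),
            class = "ratio_matrix")
}

#' @export
as.matrix.ratio_matrix <- function(x, ...) x$values

#' @export
dim.ratio_matrix <- function(x) dim(x$values)

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("<ratio_matrix> %d pairs x %d genes\n",
              nrow(x$values), ncol(x$values)))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("  missing cells: %d\n", nmiss))
  med <- stats::median(x$values, na.rm = TRUE)
  cat(sprintf("  median ratio: %.3f\n", med))
  invisible(x)
}

#' Write / read an expression-ratio matrix as CSV
#'
#' The on-disk dialect is genes in rows and pairs in columns: a header row of
#' pair IDs and a first column of gene symbols, followed by one column of
#' public IDs.
#'
#' @param x a \code{ratio_matrix}.
#' @param path file path.
#' @return \code{write_ratio_csv} returns \code{path} invisibly;
#'   \code{read_ratio_csv} returns a \code{ratio_matrix}.
#' @export
write_ratio_csv <- function(x, path) {
  stopifnot(inherits(x, "ratio_matrix"))
  df <- data.frame(symbol = x$genes$symbol,
                   public_id = x$genes$public_id,
                   t(x$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratio_csv
#' @export
read_ratio_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("symbol", "public_id") %in% names(df)))
    stop("not a ratio-matrix CSV: expected `symbol` and `public_id` columns")
  vals <- t(as.matrix(df[, setdiff(names(df), c("symbol", "public_id")),
                         drop = FALSE]))
  genes <- df[, c("symbol", "public_id"), drop = FALSE]
  ratio_matrix(vals, genes = genes, pair_ids = rownames(vals))
}

# log2 values with input checking, shared by downstream modules
log2_ratios <- function(x) {
  if (inherits(x, "ratio_matrix")) x <- x$values
  x <- as.matrix(x)
  log2(x)
}
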