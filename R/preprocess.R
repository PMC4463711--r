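#' Two-channel array scan
#'
#' Spot-level data for one hybridization: per-probe Cy5 (case) and Cy3
#' (control) foreground and background intensities plus a quality flag
#' (GenePix convention: 0 = good, negative = bad). Preprocessing stages are
#' tracked on the object and enforced in order: quality filtering, background
#' correction, global normalization, ratio computation.
#'
#' @param spots data.frame with columns \code{probe_id}, \code{gene_symbol},
#'   \code{f_cy5}, \code{b_cy5}, \code{f_cy3}, \code{b_cy3}, \code{qc_flag}.
#' @param pair_id identifier of the case-control pair hybridized on the array.
#' @return An object of class \code{array_scan}.
#' @export
array_scan <- function(spots, pair_id) {
  need <- c("probe_id", "gene_symbol", "f_cy5", "b_cy5", "f_cy3", "b_cy3",
            "qc_flag")
  if (!all(need %in% names(spots)))
    stop("array_scan needs columns: ", paste(need, collapse = ", "))
  ints <- as.matrix(spots[, c("f_cy5", "b_cy5", "f_cy3", "b_cy3")])
  if (any(!is.finite(ints)) || any(ints < 0))
    stop("intensities must be finite and non-negative")
  if (anyDuplicated(spots$probe_id))
    stop("probe_ids must be unique within a scan")
  structure(as.data.frame(spots), pair_id = as.character(pair_id),
            stages = character(0), class = c("array_scan", "data.frame"))
}

#' @export
print.array_scan <- function(x, ...) {
  st <- attr(x, "stages")
  cat(sprintf("<array_scan> pair %s: %d spots [%s]\n", attr(x, "pair_id"),
              nrow(x), if (length(st)) paste(st, collapse = " > ") else "raw"))
  invisible(x)
}

has_stage <- function(scan, stage) stage %in% attr(scan, "stages")

add_stage <- function(scan, stage) {
  attr(scan, "stages") <- c(attr(scan, "stages"), stage)
  scan
}

require_stage <- function(scan, stage, caller) {
  if (!has_stage(scan, stage))
    stop(sprintf("%s() requires a scan that has passed %s(); run the pipeline in order qc_filter -> background_correct -> global_normalize",
                 caller, stage), call. = FALSE)
}

#' Quality-filter an array scan
#'
#' Removes spots whose quality flag marks them as failed (negative flag,
#' GenePix convention). If every spot of some gene is removed, the gene will
#' surface as a missing cell downstream; a warning reports it here.
#'
#' @param scan an \code{\link{array_scan}}.
#' @return The filtered scan, with the number of removed spots recorded in
#'   attribute \code{"n_removed"}.
#' @export
qc_filter <- function(scan) {
  stopifnot(inherits(scan, "array_scan"))
  bad <- scan$qc_flag < 0
  lost <- setdiff(unique(scan$gene_symbol[bad]),
                  unique(scan$gene_symbol[!bad]))
  if (length(lost))
    warning(sprintf("pair %s: all spots removed for gene(s) %s; cell(s) will be missing",
                    attr(scan, "pair_id"), paste(lost, collapse = ", ")))
  out <- scan[!bad, , drop = FALSE]
  attr(out, "pair_id") <- attr(scan, "pair_id")
  attr(out, "stages") <- attr(scan, "stages")
  attr(out, "n_removed") <- sum(bad)
  class(out) <- class(scan)
  add_stage(out, "qc_filter")
}

#' Background-correct an array scan
#'
#' Subtracts the per-spot background from the foreground in each channel,
#' flooring the result at a positive constant so downstream ratios stay
#' defined.
#'
#' @param scan a quality-filtered \code{\link{array_scan}}.
#' @param floor positive lower bound for corrected intensities (default 1).
#' @return The scan with \code{f_cy5}/\code{f_cy3} replaced by corrected
#'   intensities and backgrounds zeroed.
#' @export
background_correct <- function(scan, floor = 1) {
  stopifnot(inherits(scan, "array_scan"))
  require_stage(scan, "qc_filter", "background_correct")
  if (floor <= 0) stop("`floor` must be positive")
  scan$f_cy5 <- pmax(scan$f_cy5 - scan$b_cy5, floor)
  scan$f_cy3 <- pmax(scan$f_cy3 - scan$b_cy3, floor)
  scan$b_cy5 <- 0
  scan$b_cy3 <- 0
  add_stage(scan, "background_correct")
}

#' Globally normalize the two channels of a scan
#'
#' Rescales the Cy5 (case) channel by a single constant so the two channels
#' are comparable, using all retained spots. Two estimators of the constant
#' are offered: \code{"sum"} (total-intensity balance: the Cy5 sum is scaled
#' to equal the Cy3 sum) and \code{"median"} (the median spot-wise Cy5/Cy3
#' ratio is scaled to 1). Total-intensity balance assumes up- and
#' down-regulation roughly cancel across the panel; the median is robust to
#' asymmetric differential expression as long as under half the genes move.
#'
#' @param scan a background-corrected \code{\link{array_scan}}.
#' @param method \code{"sum"} (default) or \code{"median"}.
#' @return The scan with the Cy5 channel rescaled; the constant applied is
#'   recorded in attribute \code{"norm_constant"}.
#' @export
global_normalize <- function(scan, method = c("sum", "median")) {
  stopifnot(inherits(scan, "array_scan"))
  require_stage(scan, "background_correct", "global_normalize")
  method <- match.arg(method)
  if (nrow(scan) == 0) stop("no spots left to normalize")
  s5 <- sum(scan$f_cy5)
  s3 <- sum(scan$f_cy3)
  if (s5 <= 0 || s3 <= 0) stop("zero total intensity in a channel")
  k <- switch(method,
              sum = s3 / s5,
              median = 1 / stats::median(scan$f_cy5 / scan$f_cy3))
  scan$f_cy5 <- scan$f_cy5 * k
  scan <- add_stage(scan, "global_normalize")
  attr(scan, "norm_constant") <- k
  attr(scan, "norm_method") <- method
  scan
}

#' Build the per-pair expression-ratio matrix from preprocessed scans
#'
#' For each scan (pair) and each gene of the target panel, averages the
#' corrected intensities of duplicate spots per channel and takes the
#' Cy5/Cy3 ratio (case over control). Genes absent from a scan give missing
#' cells with a warning; genes missing in more than \code{max_missing} of
#' pairs are dropped from the panel with a warning.
#'
#' @param scans list of fully preprocessed \code{\link{array_scan}} objects
#'   (quality-filtered, background-corrected, normalized).
#' @param panel character vector of gene symbols, or a data.frame with
#'   columns \code{symbol} and \code{public_id}.
#' @param max_missing maximum tolerated fraction of missing pairs per gene
#'   before the gene is dropped (default 0.2).
#' @return A \code{\link{ratio_matrix}}.
#' @export
compute_ratio_matrix <- function(scans, panel, max_missing = 0.2) {
  if (inherits(scans, "array_scan")) scans <- list(scans)
  stopifnot(length(scans) > 0, all(vapply(scans, inherits, TRUE, "array_scan")))
  for (s in scans) require_stage(s, "global_normalize", "compute_ratio_matrix")
  if (is.data.frame(panel)) {
    genes <- panel[, intersect(c("symbol", "public_id", "gene_name"),
                               names(panel)), drop = FALSE]
  } else {
    genes <- data.frame(symbol = as.character(panel),
                        public_id = NA_character_, stringsAsFactors = FALSE)
  }
  syms <- genes$symbol
  vals <- t(vapply(scans, function(s) {
    c5 <- vapply(split(s$f_cy5, s$gene_symbol)[syms],
                 function(v) if (is.null(v)) NA_real_ else mean(v), 0)
    c3 <- vapply(split(s$f_cy3, s$gene_symbol)[syms],
                 function(v) if (is.null(v)) NA_real_ else mean(v), 0)
    c5 / c3
  }, numeric(length(syms))))
  pair_ids <- vapply(scans, attr, "", "pair_id")
  n_missing <- colSums(is.na(vals))
  if (any(n_missing > 0))
    warning(sprintf("%d missing cell(s) across %d gene(s)",
                    sum(n_missing), sum(n_missing > 0)))
  drop <- n_missing / nrow(vals) > max_missing
  if (any(drop)) {
    warning(sprintf("dropping %d gene(s) missing in > %.0f%% of pairs: %s",
                    sum(drop), 100 * max_missing,
                    paste(syms[drop], collapse = ", ")))
    vals <- vals[, !drop, drop = FALSE]
    genes <- genes[!drop, , drop = FALSE]
  }
  ratio_matrix(vals, genes = genes, pair_ids = pair_ids)
}

#' Run the full preprocessing chain on raw scans
#'
#' Convenience wrapper applying \code{\link{qc_filter}},
#' \code{\link{background_correct}} and \code{\link{global_normalize}} to
#' each scan and assembling the ratio matrix.
#'
#' @inheritParams compute_ratio_matrix
#' @inheritParams background_correct
#' @inheritParams global_normalize
#' @return A \code{\link{ratio_matrix}}; normalization constants per pair are
#'   attached as attribute \code{"norm_constants"}.
#' @export
preprocess_scans <- function(scans, panel, method = c("sum", "median"),
                             floor = 1, max_missing = 0.2) {
  method <- match.arg(method)
  done <- lapply(scans, function(s)
    global_normalize(background_correct(qc_filter(s), floor = floor),
                     method = method))
  rm <- compute_ratio_matrix(done, panel, max_missing = max_missing)
  attr(rm, "norm_constants") <- vapply(done, attr, 0, "norm_constant")
  rm
}

# GenePix-like TSV I/O ------------------------------------------------------

#' Read / write GenePix-style scan files
#'
#' Scans are serialized as tab-separated tables with the GenePix column
#' convention: \code{Block, Column, Row, Name, ID, F635 Median, B635 Median,
#' F532 Median, B532 Median, Flags} (635 nm = Cy5 case channel, 532 nm = Cy3
#' control channel). Unknown columns are ignored on read.
#'
#' @param scan an \code{\link{array_scan}}.
#' @param path file path.
#' @param pair_id pair identifier to attach on read (default: file name).
#' @return \code{write_scan} returns \code{path} invisibly; \code{read_scan}
#'   returns a raw \code{\link{array_scan}}.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "array_scan"))
  n <- nrow(scan)
  df <- data.frame(
    Block = 1L, Column = seq_len(n), Row = 1L,
    Name = scan$gene_symbol, ID = scan$probe_id,
    `F635 Median` = scan$f_cy5, `B635 Median` = scan$b_cy5,
    `F532 Median` = scan$f_cy3, `B532 Median` = scan$b_cy3,
    Flags = scan$qc_flag, check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path, pair_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Name", "ID", "F635 Median", "B635 Median", "F532 Median",
            "B532 Median", "Flags")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("scan file lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(pair_id))
    pair_id <- sub("\\.[^.]+$", "", basename(path))
  array_scan(data.frame(
    probe_id = df$ID, gene_symbol = df$Name,
    f_cy5 = df$`F635 Median`, b_cy5 = df$`B635 Median`,
    f_cy3 = df$`F532 Median`, b_cy3 = df$`B532 Median`,
    qc_flag = df$Flags, stringsAsFactors = FALSE
  ), pair_id = pair_id)
}
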