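#' Discretize expression values into three states
#'
#' Per-gene three-state discretization used for mutual-information
#' estimation: values below mean - k*sd map to -1, above mean + k*sd to +1,
#' and the central band to 0. Statistics are computed per gene over samples
#' on the log2 scale. Constant genes map to all-zero states with a warning.
#'
#' @param x samples x genes numeric matrix (log2 expression or log2 ratios),
#'   or a \code{\link{ratio_matrix}} (log2 is taken).
#' @param k_sigma width of the central band in SD units (> 0; default 1).
#' @return An object of class \code{discretized_matrix}: list with
#'   \code{states} (integer matrix in \{-1, 0, +1\}) and \code{thresholds}
#'   (per-gene low/high cut points).
#' @export
discretize_expression <- function(x, k_sigma = 1) {
  if (inherits(x, "ratio_matrix")) x <- log2_ratios(x)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("`x` must be finite")
  k_sigma <- check_positive(k_sigma, "k_sigma")
  mu <- colMeans(x)
  sds <- col_sds(x)
  if (any(sds == 0))
    warning(sprintf("%d constant gene(s) discretized to all-zero states",
                    sum(sds == 0)))
  lo <- mu - k_sigma * sds
  hi <- mu + k_sigma * sds
  n <- nrow(x)
  states <- matrix(0L, n, ncol(x), dimnames = dimnames(x))
  states[x < rep(lo, each = n)] <- -1L
  states[x > rep(hi, each = n)] <- 1L
  states[, sds == 0] <- 0L
  structure(list(states = states,
                 thresholds = data.frame(low = lo, high = hi)),
            class = "discretized_matrix")
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat(sprintf("<discretized_matrix> %d samples x %d genes; state frequencies:\n",
              nrow(x$states), ncol(x$states)))
  print(table(x$states) / length(x$states))
  invisible(x)
}

#' Empirical mutual information of two discrete sequences
#'
#' Plug-in estimate in bits: I(X;Y) = sum over observed cells of
#' p(x,y) log2\[p(x,y) / (p(x) p(y))\] with empirical joint frequencies;
#' zero-count cells contribute nothing. Nonnegative up to floating error and
#' symmetric in its arguments. No small-sample bias correction is applied.
#'
#' @param x,y equal-length vectors of discrete values (integer, character or
#'   factor).
#' @return Mutual information in bits (single nonnegative number).
#' @examples
#' mutual_information(c(0, 0, 1, 1), c("a", "a", "b", "b"))  # 1 bit
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) == 0) stop("sequences must be non-empty")
  xi <- as.integer(factor(x))
  yi <- as.integer(factor(y))
  mi_codes(xi, max(xi), yi, max(yi))
}

# fast MI over integer codes 1..kx / 1..ky (internal hot path)
mi_codes <- function(x, kx, y, ky) {
  n <- length(x)
  joint <- tabulate((x - 1L) * ky + y, kx * ky)
  px <- tabulate(x, kx) / n
  py <- tabulate(y, ky) / n
  pj <- joint / n
  # expected joint under independence, laid out to match the tabulate index
  # (x - 1) * ky + y: x varies slowest
  pe <- rep(px, each = ky) * rep(py, times = kx)
  nz <- pj > 0
  max(sum(pj[nz] * log2(pj[nz] / pe[nz])), 0)
}

#' Minimum-redundancy maximum-relevance gene ranking
#'
#' Greedy incremental mRMR selection on discretized expression: the first
#' gene maximizes mutual information with the class label (relevance); each
#' subsequent step picks the gene maximizing relevance minus (MID, additive)
#' or divided by (MIQ, quotient) the mean mutual information with the
#' already-selected genes (redundancy). Ties are broken toward the lower
#' gene index, making the ranking deterministic.
#'
#' @param disc a \code{\link{discretize_expression}} result, or an integer
#'   states matrix (samples x genes).
#' @param labels per-sample class labels (two classes, both present).
#' @param n number of genes to rank (<= number of genes).
#' @param criterion \code{"MID"} (default) or \code{"MIQ"}; MIQ divides by
#'   \code{max(mean redundancy, 1e-12)}.
#' @return An object of class \code{mrmr_ranking}: list with
#'   \code{ordered_genes} (column indices in selection order),
#'   \code{symbols}, \code{scores} (criterion value at each step),
#'   \code{relevance} (MI of every gene with the label), and
#'   \code{criterion}.
#' @export
select_mrmr <- function(disc, labels, n, criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  states <- if (inherits(disc, "discretized_matrix")) disc$states else
    as.matrix(disc)
  G <- ncol(states)
  n <- check_count(n, "n")
  if (n > G) stop("`n` exceeds the number of genes")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("both classes must be present in `labels`")
  if (length(labels) != nrow(states))
    stop("`labels` must have one entry per sample")
  codes <- states + 2L  # {-1,0,1} -> 1..3
  y <- as.integer(labels)
  ky <- nlevels(labels)
  relevance <- vapply(seq_len(G), function(g)
    mi_codes(codes[, g], 3L, y, ky), 0)
  if (all(relevance == 0))
    warning("no gene carries label information; ranking falls back to gene index")

  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(G)  # cumulative MI with selected genes
  remaining <- rep(TRUE, G)
  eps <- 1e-12
  for (step in seq_len(n)) {
    cand <- which(remaining)
    crit <- if (step == 1L) relevance[cand] else {
      mean_red <- red_sum[cand] / length(selected)
      if (criterion == "MID") relevance[cand] - mean_red
      else relevance[cand] / pmax(mean_red, eps)
    }
    pick <- cand[which.max(crit)]  # which.max takes the first max: lower index
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    remaining[pick] <- FALSE
    if (step < n) {
      upd <- which(remaining)
      red_sum[upd] <- red_sum[upd] + vapply(upd, function(g)
        mi_codes(codes[, g], 3L, codes[, pick], 3L), 0)
    }
  }
  structure(list(ordered_genes = selected,
                 symbols = colnames(states)[selected],
                 scores = scores, relevance = relevance,
                 criterion = criterion),
            class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat(sprintf("<mrmr_ranking> %d genes (%s criterion)\n",
              length(x$ordered_genes), x$criterion))
  top <- utils::head(x$ordered_genes, 10)
  lab <- if (!is.null(x$symbols)) utils::head(x$symbols, 10) else top
  cat("  top:", paste(lab, collapse = ", "),
      if (length(x$ordered_genes) > 10) "..." else "", "\n")
  invisible(x)
}
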