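#' Screen for differentially expressed genes
#'
#' Applies the dual fold-change / significance rule to a per-pair
#' expression-ratio matrix. For each gene, the mean and SEM of the per-pair
#' case/control ratios are computed on the ratio scale, and a two-sided
#' one-sample Student t-test of the log2 ratios against 0 gives the raw
#' p-value, Bonferroni-adjusted over the number of genes actually tested. A
#' gene is called up-regulated if its mean fold change exceeds \code{fc_up}
#' and the adjusted p-value is below \code{alpha}; down-regulated if the mean
#' fold change is below \code{fc_down} under the same significance
#' requirement; otherwise not significant.
#'
#' @param x a \code{\link{ratio_matrix}} (or plain positive matrix, pairs in
#'   rows).
#' @param fc_up fold-change threshold for up-regulation (default 2).
#' @param fc_down fold-change threshold for down-regulation (default 0.5).
#' @param alpha significance level on the Bonferroni-adjusted p (default 0.05).
#' @param min_pairs minimum usable pairs per gene; genes below it are
#'   reported with \code{call = "ns"} and \code{flagged = TRUE}, never
#'   silently dropped (default 3).
#' @return An object of class \code{de_screen}: a data.frame with one row per
#'   gene (\code{gene_name}, \code{symbol}, \code{public_id}, \code{n_pairs},
#'   \code{mean_fc}, \code{sem_fc}, \code{p_raw}, \code{p_adj}, \code{call},
#'   \code{flagged}), sorted by call (down, up, ns) then symbol, with the
#'   number of genes used for the Bonferroni correction in attribute
#'   \code{"n_tested"}.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_pairs = 20, seed = 1))
#' de <- screen_de(cohort$ratios)
#' table(de$call)
#' @export
screen_de <- function(x, fc_up = 2, fc_down = 0.5, alpha = 0.05,
                      min_pairs = 3) {
  genes <- if (inherits(x, "ratio_matrix")) x$genes else NULL
  vals <- if (inherits(x, "ratio_matrix")) x$values else as.matrix(x)
  if (fc_up <= fc_down) stop("`fc_up` must exceed `fc_down`")
  check_fraction(alpha, "alpha")
  G <- ncol(vals)
  lr <- log2(vals)
  res <- lapply(seq_len(G), function(g) {
    r <- vals[, g]
    ok <- !is.na(r)
    n <- sum(ok)
    if (n < min_pairs)
      return(list(n = n, mean_fc = if (n) mean(r[ok]) else NA_real_,
                  sem_fc = NA_real_, p = NA_real_, flagged = TRUE))
    v <- lr[ok, g]
    p <- if (stats::sd(v) == 0) {
      # degenerate: constant log ratio carries no sampling variability;
      # a constant 1 is a textbook null, anything else is unambiguous
      if (mean(v) == 0) NA_real_ else 0
    } else stats::t.test(v, mu = 0, alternative = "two.sided")$p.value
    list(n = n, mean_fc = mean(r[ok]),
         sem_fc = stats::sd(r[ok]) / sqrt(n),
         p = p, flagged = FALSE)
  })
  p_raw <- vapply(res, `[[`, 0, "p")
  n_tested <- sum(!is.na(p_raw))
  p_adj <- pmin(1, p_raw * n_tested)
  mean_fc <- vapply(res, `[[`, 0, "mean_fc")
  flagged <- vapply(res, `[[`, TRUE, "flagged")
  call <- rep("ns", G)
  sig <- !is.na(p_adj) & p_adj < alpha & !flagged
  call[sig & mean_fc > fc_up] <- "up"
  call[sig & mean_fc < fc_down] <- "down"
  out <- data.frame(
    gene_name = if (!is.null(genes) && "gene_name" %in% names(genes))
      genes$gene_name else NA_character_,
    symbol = if (!is.null(genes)) genes$symbol else
      (colnames(vals) %||% sprintf("G%03d", seq_len(G))),
    public_id = if (!is.null(genes)) genes$public_id else NA_character_,
    n_pairs = vapply(res, `[[`, 0L, "n"),
    mean_fc = mean_fc,
    sem_fc = vapply(res, `[[`, 0, "sem_fc"),
    p_raw = p_raw, p_adj = p_adj, call = call, flagged = flagged,
    stringsAsFactors = FALSE
  )
  out <- out[order(factor(out$call, levels = c("down", "up", "ns")),
                   out$symbol), ]
  rownames(out) <- NULL
  structure(out, n_tested = n_tested, alpha = alpha, fc_up = fc_up,
            fc_down = fc_down, class = c("de_screen", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.de_screen <- function(x, ...) {
  cat(sprintf("<de_screen> %d genes tested (Bonferroni over %d)\n",
              nrow(x), attr(x, "n_tested")))
  cat(sprintf("  calls: %d down, %d up, %d ns\n",
              sum(x$call == "down"), sum(x$call == "up"), sum(x$call == "ns")))
  invisible(x)
}

#' @export
summary.de_screen <- function(object, ...) {
  cat(format_table1(object), sep = "\n")
  invisible(object)
}

#' Render differential-expression calls as a publication-style table
#'
#' Formats the significant genes as a text table, down-regulated block first
#' and then up-regulated, with fold change rendered \code{"mean +/- SEM"} to
#' two decimals.
#'
#' @param results a \code{\link{screen_de}} result.
#' @return Character vector, one element per line.
#' @export
format_table1 <- function(results) {
  stopifnot(inherits(results, "de_screen"))
  render <- function(block) {
    if (nrow(block) == 0) return(character(0))
    sprintf("%s\t%s\t%s\t%.2f ± %.2f",
            ifelse(is.na(block$gene_name), block$symbol, block$gene_name),
            block$symbol, block$public_id, block$mean_fc, block$sem_fc)
  }
  header <- "Gene Name\tSymbol\tPublic ID\tFold Change"
  down <- results[results$call == "down", , drop = FALSE]
  up <- results[results$call == "up", , drop = FALSE]
  out <- header
  if (nrow(down)) out <- c(out, "down-regulated genes", render(down))
  if (nrow(up)) out <- c(out, "up-regulated genes", render(up))
  out
}
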