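#' Relative qPCR fold change by the comparative Ct method
#'
#' Computes 2^-ddCt for a target gene: per sample, technical replicates are
#' averaged and dCt = Ct(target) - Ct(housekeeper); then
#' ddCt = mean dCt(case) - mean dCt(control), and the returned relative
#' fold change is 2^-ddCt.
#'
#' @param table a \code{\link{ct_table}} (long-format: \code{sample_id},
#'   \code{group}, \code{gene}, \code{ct}).
#' @param gene target gene symbol.
#' @param housekeeper housekeeping gene symbol; defaults to the table's
#'   attribute (beta-actin in the synthetic generator).
#' @return Relative fold change (single positive number) with the ddCt value
#'   in attribute \code{"ddct"}.
#' @examples
#' ct <- simulate_ct_table("BIRC3", ddct_truth = -2, ct_sd = 1e-9)
#' ddct_fold_change(ct, "BIRC3")  # 4
#' @export
ddct_fold_change <- function(table, gene,
                             housekeeper = attr(table, "housekeeper")) {
  stopifnot(is.data.frame(table))
  if (is.null(housekeeper)) stop("no housekeeping gene specified")
  if (!gene %in% table$gene) stop(sprintf("gene '%s' absent from table", gene))
  mean_ct <- function(g) {
    sub <- table[table$gene == g, , drop = FALSE]
    out <- tapply(sub$ct, sub$sample_id, mean)  # replicates averaged
    out
  }
  hk <- mean_ct(housekeeper)
  tg <- mean_ct(gene)
  no_hk <- setdiff(names(tg), names(hk))
  if (length(no_hk))
    stop("missing housekeeping Ct for sample(s): ",
         paste(no_hk, collapse = ", "))
  dct <- tg - hk[names(tg)]
  grp <- table$group[match(names(tg), table$sample_id)]
  for (g in c("case", "control"))
    if (!g %in% grp) stop(sprintf("gene '%s' has no '%s' samples", gene, g))
  ddct <- mean(dct[grp == "case"]) - mean(dct[grp == "control"])
  structure(2^(-ddct), ddct = ddct)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided test of a location difference between two independent groups.
#' For combined sample sizes up to 20 the p-value is computed by full
#' enumeration of all rank assignments (valid under ties, which are handled
#' by mid-ranks); for larger samples the normal approximation with the
#' tie-corrected variance and continuity correction is used. The method
#' actually applied is recorded on the result.
#'
#' @param values_case,values_control numeric vectors (non-empty).
#' @param method \code{"auto"} (default: exact up to combined n = 20, normal
#'   beyond), or force \code{"exact"} / \code{"normal"}.
#' @return List with \code{U} (Mann-Whitney statistic of the case group),
#'   \code{p} (two-sided), and \code{method} (\code{"exact"} or
#'   \code{"normal"}).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(values_case, values_control,
                          method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(values_case)
  y <- as.numeric(values_control)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  nx <- length(x)
  ny <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(all_v)) == 1) {
    warning("all values tied across both groups; p = 1")
    return(list(U = U, p = 1, method = "degenerate"))
  }
  m <- nx * ny
  if (method == "auto") method <- if (nx + ny <= 20) "exact" else "normal"
  if (method == "exact") {
    if (nx + ny > 24) stop("exact enumeration limited to combined n <= 24")
    # exact two-sided p by enumeration of all C(nx+ny, nx) assignments,
    # extremity measured as min(U, m - U) (symmetric under group swap)
    combos <- utils::combn(nx + ny, nx)
    stats_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    obs <- min(U, m - U)
    p <- mean(pmin(stats_all, m - stats_all) <= obs)
    list(U = U, p = p, method = "exact")
  } else {
    n <- nx + ny
    ties <- table(all_v)
    sigma2 <- m / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - m / 2)
    z <- (abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-z))
    list(U = U, p = p, method = "normal")
  }
}

#' Age-association screen for signature genes
#'
#' For each gene, tests whether expression depends on age two ways: a
#' Pearson linear correlation of log2 ratio against age, and a one-way
#' ANOVA across four age groups formed by the sample age quartiles. Genes
#' significant at \code{alpha} on either test are flagged. Constant genes
#' are reported as \code{NA} with a warning rather than failing.
#'
#' @param x a \code{\link{ratio_matrix}} or cases x genes matrix of ratios.
#' @param ages numeric ages, one per row of \code{x} (>= 2 distinct values).
#' @param genes gene symbols to test (default: all columns).
#' @param alpha flagging level (default 0.05).
#' @return An object of class \code{age_association}: data.frame per gene
#'   with \code{r}, \code{p_cor}, \code{F}, \code{p_anova}, \code{flagged};
#'   the quartile boundaries are stored in attribute \code{"age_breaks"}.
#' @export
age_association <- function(x, ages, genes = NULL, alpha = 0.05) {
  vals <- if (inherits(x, "ratio_matrix")) x$values else as.matrix(x)
  if (length(ages) != nrow(vals))
    stop("`ages` must have one entry per sample")
  if (length(unique(ages)) < 2) stop("need >= 2 distinct ages")
  if (is.null(genes)) genes <- colnames(vals)
  genes <- intersect(genes, colnames(vals))
  if (length(genes) == 0) stop("no requested gene found in the matrix")
  breaks <- unique(stats::quantile(ages, probs = seq(0, 1, 0.25)))
  groups <- cut(ages, breaks = breaks, include.lowest = TRUE)
  lr <- log2(vals[, genes, drop = FALSE])
  any_const <- FALSE
  rows <- lapply(genes, function(g) {
    v <- lr[, g]
    ok <- !is.na(v)
    if (stats::sd(v[ok]) == 0) {
      any_const <<- TRUE
      return(data.frame(gene = g, r = NA_real_, p_cor = NA_real_,
                        F = NA_real_, p_anova = NA_real_, flagged = FALSE,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(v[ok], ages[ok], method = "pearson")
    av <- stats::anova(stats::lm(v[ok] ~ groups[ok]))
    data.frame(gene = g, r = unname(ct$estimate), p_cor = ct$p.value,
               F = av$`F value`[1], p_anova = av$`Pr(>F)`[1],
               flagged = ct$p.value < alpha || av$`Pr(>F)`[1] < alpha,
               stringsAsFactors = FALSE)
  })
  if (any_const)
    warning("constant gene(s): correlation undefined, reported as NA")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, age_breaks = breaks,
            class = c("age_association", "data.frame"))
}

#' @export
print.age_association <- function(x, ...) {
  cat(sprintf("<age_association> %d genes; %d flagged at either test\n",
              nrow(x), sum(x$flagged, na.rm = TRUE)))
  cat("  age-group boundaries:",
      paste(round(attr(x, "age_breaks"), 1), collapse = ", "), "\n")
  invisible(x)
}
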