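#' Leave-one-out signature-size sweep
#'
#' The signature-identification engine: for every held-out sample, the
#' feature pool and the mRMR ranking are rebuilt from the remaining training
#' samples only, and for each signature size n = 1..n_max one linear SVM is
#' fit on the top-n genes and used to predict the held-out sample. The
#' held-out sample never touches feature screening, discretization
#' thresholds, ranking, or standardization. With 160 samples and sizes 1-50
#' this builds exactly 8000 SVM models.
#'
#' The feature pool per fold is, in order of precedence: a fixed \code{pool}
#' (the protocol of screening once on the full cohort and re-ranking per
#' fold), or — when \code{de_first = TRUE} and \code{pairs} is supplied — the
#' genes called differential by \code{\link{screen_de}} on the complete
#' case-control pairs within the fold's training samples (fully nested
#' screening), or else all genes.
#'
#' @param x samples x genes numeric matrix of log2 expression, with gene
#'   symbols as column names.
#' @param labels per-sample class labels (two classes; \code{"case"} is the
#'   positive class if present).
#' @param n_max largest signature size to evaluate (default 50).
#' @param pool optional fixed feature pool: gene symbols or column indices.
#' @param de_first rebuild the pool per fold by differential-expression
#'   screening (requires \code{pairs}); default \code{TRUE} when no
#'   \code{pool} is given.
#' @param pairs per-sample pair identifiers, required for \code{de_first}.
#' @param cost_c SVM cost used for every model (default 0.5).
#' @param criterion,k_sigma passed to \code{\link{select_mrmr}} /
#'   \code{\link{discretize_expression}}.
#' @param fc_up,fc_down,alpha screening thresholds for the per-fold pool.
#' @return An object of class \code{signature_curve}: \code{accuracy_by_n}
#'   (LOOCV accuracy for each size), \code{per_fold_selections} (ranked gene
#'   list per fold), \code{models_built}, \code{n_folds}, \code{n_max}.
#' @export
loocv_size_sweep <- function(x, labels, n_max = 50, pool = NULL,
                             de_first = is.null(pool), pairs = NULL,
                             cost_c = 0.5, criterion = "MID", k_sigma = 1,
                             fc_up = 2, fc_down = 0.5, alpha = 0.05) {
  x <- as.matrix(x)
  n_samples <- nrow(x)
  if (n_samples < 3) stop("need at least 3 samples")
  n_max <- check_count(n_max, "n_max")
  if (n_max > ncol(x)) stop("`n_max` exceeds the number of available genes")
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("`labels` must have exactly two classes")
  syms <- colnames(x) %||% sprintf("G%03d", seq_len(ncol(x)))
  colnames(x) <- syms
  if (!is.null(pool)) {
    pool <- if (is.character(pool)) match(pool, syms) else as.integer(pool)
    if (any(is.na(pool)) || any(pool < 1) || any(pool > ncol(x)))
      stop("`pool` contains unknown genes")
    de_first <- FALSE
  }
  if (de_first && is.null(pairs))
    stop("`de_first = TRUE` requires per-sample `pairs`")

  correct <- integer(n_max)
  avail <- integer(n_max)   # folds in which size n was evaluable
  models_built <- 0L
  selections <- vector("list", n_samples)
  truncated <- FALSE
  for (i in seq_len(n_samples)) {
    tr <- setdiff(seq_len(n_samples), i)
    y_tr <- labels[tr]
    pool_i <- if (!is.null(pool)) pool else if (de_first) {
      fold_pool_by_screening(x, labels, pairs, tr, fc_up, fc_down, alpha)
    } else seq_len(ncol(x))
    if (length(pool_i) == 0) pool_i <- seq_len(ncol(x))
    n_i <- min(n_max, length(pool_i))
    if (n_i < n_max) truncated <- TRUE
    disc <- suppressWarnings(
      discretize_expression(x[tr, pool_i, drop = FALSE], k_sigma = k_sigma))
    rank_i <- select_mrmr(disc, y_tr, n = n_i, criterion = criterion)
    ranked <- pool_i[rank_i$ordered_genes]
    selections[[i]] <- syms[ranked]
    for (n in seq_len(n_i)) {
      m <- train_svm(x[tr, ranked[seq_len(n)], drop = FALSE], y_tr,
                     cost_c = cost_c)
      pred <- predict(m, x[i, ranked[seq_len(n)], drop = FALSE])
      models_built <- models_built + 1L
      avail[n] <- avail[n] + 1L
      if (pred == as.character(labels[i])) correct[n] <- correct[n] + 1L
    }
  }
  if (truncated)
    warning("feature pool smaller than `n_max` in some folds; curve truncated there")
  accuracy <- ifelse(avail > 0, correct / avail, NA_real_)
  structure(list(accuracy_by_n = stats::setNames(accuracy, seq_len(n_max)),
                 per_fold_selections = selections,
                 models_built = models_built, n_folds = n_samples,
                 n_max = n_max, cost_c = cost_c),
            class = "signature_curve")
}

# DE screen restricted to the complete case-control pairs among training rows
fold_pool_by_screening <- function(x, labels, pairs, tr, fc_up, fc_down,
                                   alpha) {
  pairs <- as.character(pairs)
  tr_pairs <- pairs[tr]
  tab <- table(tr_pairs)
  complete <- names(tab)[tab == 2]
  if (length(complete) < 3) return(integer(0))
  pos <- if ("case" %in% levels(labels)) "case" else levels(labels)[1]
  case_rows <- tr[labels[tr] == pos]
  ctrl_rows <- setdiff(tr, case_rows)
  case_rows <- case_rows[match(complete, pairs[case_rows])]
  ctrl_rows <- ctrl_rows[match(complete, pairs[ctrl_rows])]
  if (any(is.na(case_rows)) || any(is.na(ctrl_rows))) return(integer(0))
  ratios <- 2^(x[case_rows, , drop = FALSE] - x[ctrl_rows, , drop = FALSE])
  de <- screen_de(ratios, fc_up = fc_up, fc_down = fc_down, alpha = alpha)
  which(colnames(x) %in% de$symbol[de$call != "ns"])
}

#' @export
print.signature_curve <- function(x, ...) {
  acc <- x$accuracy_by_n
  best <- which.max(acc)
  cat(sprintf("<signature_curve> %d folds x sizes 1..%d (%d SVM models)\n",
              x$n_folds, x$n_max, x$models_built))
  cat(sprintf("  best LOOCV accuracy %.1f%% at n = %d; accuracy at n = 20: %s\n",
              100 * acc[best], best,
              if (x$n_max >= 20) sprintf("%.1f%%", 100 * acc[20]) else "-"))
  invisible(x)
}

#' @export
plot.signature_curve <- function(x, ...) {
  graphics::plot(as.integer(names(x$accuracy_by_n)), x$accuracy_by_n,
                 type = "b", pch = 16, cex = 0.6,
                 xlab = "signature size n", ylab = "LOOCV accuracy",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' How often each gene enters the top-n across LOOCV folds
#'
#' @param curve a \code{\link{loocv_size_sweep}} result.
#' @param n signature size (default 20).
#' @return Named numeric vector of selection frequencies in [0, 1], sorted
#'   decreasingly.
#' @export
selection_frequencies <- function(curve, n = 20) {
  stopifnot(inherits(curve, "signature_curve"))
  tops <- unlist(lapply(curve$per_fold_selections, utils::head, n))
  sort(table(tops) / curve$n_folds, decreasing = TRUE)
}

#' Fit the final gene signature on the full training set
#'
#' Runs mRMR once on all training samples, takes the top-n genes, selects
#' the SVM cost by seeded cross-validated grid search on those genes, and
#' fits the final linear SVM. When a LOOCV curve is supplied, per-fold
#' selection frequencies for the chosen size are attached for transparency.
#'
#' @inheritParams loocv_size_sweep
#' @param n signature size (default 20).
#' @param grid candidate costs for \code{\link{grid_search_c}}; set
#'   \code{cost_c} instead to skip the search.
#' @param cost_c optional fixed cost; overrides the grid search.
#' @param folds,seed grid-search cross-validation folds and seed.
#' @param curve optional \code{\link{loocv_size_sweep}} result.
#' @return An object of class \code{kbd_signature}: \code{genes} (symbols),
#'   \code{svm} (the \code{\link{train_svm}} fit), \code{ranking},
#'   \code{cost_c}, and \code{selection_freq} when a curve was given.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_pairs = 15, seed = 7))
#' sig <- kbd_signature(cohort$samples, cohort$metadata$role, n = 5,
#'                      de_first = FALSE, cost_c = 0.5)
#' print(sig)
#' @export
kbd_signature <- function(x, labels, n = 20, pool = NULL,
                          de_first = is.null(pool), pairs = NULL,
                          criterion = "MID", k_sigma = 1,
                          grid = 2^seq(-5, 15, by = 2), cost_c = NULL,
                          folds = 5, seed = 1, fc_up = 2, fc_down = 0.5,
                          alpha = 0.05, curve = NULL) {
  x <- as.matrix(x)
  syms <- colnames(x) %||% sprintf("G%03d", seq_len(ncol(x)))
  colnames(x) <- syms
  labels <- factor(labels)
  if (!is.null(pool)) {
    pool <- if (is.character(pool)) match(pool, syms) else as.integer(pool)
    if (any(is.na(pool))) stop("`pool` contains unknown genes")
  } else if (de_first) {
    if (is.null(pairs)) stop("`de_first = TRUE` requires per-sample `pairs`")
    pool <- fold_pool_by_screening(x, labels, pairs, seq_len(nrow(x)),
                                   fc_up, fc_down, alpha)
    if (length(pool) == 0) pool <- seq_len(ncol(x))
  } else pool <- seq_len(ncol(x))
  if (n > length(pool))
    stop(sprintf("`n` (%d) exceeds the feature pool size (%d)", n,
                 length(pool)))
  disc <- suppressWarnings(
    discretize_expression(x[, pool, drop = FALSE], k_sigma = k_sigma))
  ranking <- select_mrmr(disc, labels, n = n, criterion = criterion)
  genes <- syms[pool[ranking$ordered_genes]]
  Xs <- x[, genes, drop = FALSE]
  if (is.null(cost_c))
    cost_c <- as.numeric(grid_search_c(Xs, labels, grid = grid,
                                       folds = folds, seed = seed))
  svm_fit <- train_svm(Xs, labels, cost_c = cost_c)
  freq <- if (!is.null(curve)) selection_frequencies(curve, n) else NULL
  structure(list(genes = genes, svm = svm_fit, ranking = ranking,
                 n = n, cost_c = cost_c, selection_freq = freq),
            class = "kbd_signature")
}

#' @rdname kbd_signature
#' @export
finalize_signature <- kbd_signature

#' @export
print.kbd_signature <- function(x, ...) {
  cat(sprintf("<kbd_signature> %d genes, linear SVM (C = %g)\n",
              x$n, x$cost_c))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.kbd_signature <- function(object, ...) coef(object$svm)

#' @export
predict.kbd_signature <- function(object, newdata, ...) {
  predict(object$svm, newdata, ...)
}

#' Evaluate a fitted signature on an independent test set
#'
#' Predicts the test samples from their expression alone and tabulates the
#' result against the true labels, with cases as the positive class. A test
#' matrix lacking any model gene is an error; no silent imputation.
#'
#' @param object a \code{\link{kbd_signature}} or \code{\link{train_svm}}
#'   fit.
#' @param x_test samples x genes test matrix (genes matched by name).
#' @param y_test true labels.
#' @param positive label counted as positive (default \code{"case"}).
#' @return A \code{\link{confusion_table}}.
#' @export
evaluate_signature <- function(object, x_test, y_test, positive = "case") {
  pred <- predict(object, x_test)
  y <- as.character(y_test)
  if (!positive %in% y) positive <- unique(y)[1]
  confusion_table(tp = sum(pred == positive & y == positive),
                  fn = sum(pred != positive & y == positive),
                  tn = sum(pred != positive & y != positive),
                  fp = sum(pred == positive & y != positive))
}
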