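#' Train a linear soft-margin SVM on standardized expression features
#'
#' Fits a C-SVC with linear kernel (LIBSVM, via e1071) on features z-scored
#' with statistics learned from the training data only; near-constant
#' features get their scale floored so standardization never divides by
#' zero. The fitted classifier is stored in primal form (per-gene weights
#' and bias on the standardized scale), so predictions are a plain
#' \code{sign(w . z + b)}.
#'
#' @param X samples x genes numeric matrix (no missing values).
#' @param y class labels with exactly two levels, both present. The class
#'   named \code{"case"} (if present, otherwise the first level) is treated
#'   as positive.
#' @param cost_c soft-margin cost C (> 0; default 0.5).
#' @return An object of class \code{linear_svm}: weights, bias, cost,
#'   per-gene centering/scaling, gene names, class levels and positive
#'   class.
#' @export
train_svm <- function(X, y, cost_c = 0.5) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("`X` must have no missing values")
  cost_c <- check_positive(cost_c, "cost_c")
  y <- factor(y)
  if (nlevels(y) != 2 || any(tabulate(y) == 0))
    stop("`y` must contain exactly two classes, both present")
  if ("case" %in% levels(y)) y <- stats::relevel(y, "case")
  center <- colMeans(X)
  scale <- col_sds(X)
  scale[scale < 1e-8] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  fit <- e1071::svm(x = Z, y = y, kernel = "linear", cost = cost_c,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm's positive decision side is the class named first in the
  # decision-values column ("A/B" means decision > 0 -> A)
  dv <- stats::predict(fit, Z[1, , drop = FALSE], decision.values = TRUE)
  pos <- strsplit(colnames(attr(dv, "decision.values")), "/")[[1]][1]
  genes <- colnames(X) %||% sprintf("G%03d", seq_len(ncol(X)))
  structure(list(weights = stats::setNames(w, genes), bias = b,
                 cost_c = cost_c, center = center, scale = scale,
                 genes = genes, levels = levels(y), positive = pos),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d genes, C = %g, positive class '%s'\n",
              length(x$weights), x$cost_c, x$positive))
  invisible(x)
}

#' @export
coef.linear_svm <- function(object, ...) c(object$weights, bias = object$bias)

#' Predict classes (or decision values) from a linear SVM
#'
#' @param object a \code{\link{train_svm}} fit.
#' @param newdata samples x genes matrix containing at least the model's
#'   genes (matched by name when available).
#' @param type \code{"class"} (default) or \code{"decision"}.
#' @param ... unused.
#' @return Character vector of class labels, or numeric decision values.
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing_g <- setdiff(object$genes, colnames(newdata))
    if (length(missing_g))
      stop("test data lacks model gene(s): ", paste(missing_g, collapse = ", "))
    newdata <- newdata[, object$genes, drop = FALSE]
  } else if (ncol(newdata) != length(object$genes)) {
    stop("`newdata` must have one column per model gene")
  }
  Z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  d <- drop(Z %*% object$weights) + object$bias
  if (type == "decision") return(d)
  neg <- setdiff(object$levels, object$positive)
  ifelse(d > 0, object$positive, neg)
}

#' Select the SVM cost by cross-validated grid search
#'
#' Evaluates each candidate C by k-fold cross-validated accuracy (seeded
#' fold assignment) and returns the best; ties go to the smallest C, i.e.
#' the smoothest model.
#'
#' @inheritParams train_svm
#' @param grid non-empty numeric vector of candidate costs; default
#'   \code{2^seq(-5, 15, by = 2)}.
#' @param folds number of cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @return The selected cost (single number), with the per-candidate mean
#'   accuracies in attribute \code{"cv_accuracy"}.
#' @export
grid_search_c <- function(X, y, grid = 2^seq(-5, 15, by = 2), folds = 5,
                          seed = 1) {
  if (length(grid) == 0) stop("`grid` must be non-empty")
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  folds <- max(2L, min(check_count(folds, "folds", 2L), n))
  fold_id <- with_seed(derive_seed(seed, "gridsearch"),
                       sample(rep_len(seq_len(folds), n)))
  acc <- vapply(grid, function(cc) {
    correct <- 0L
    for (f in seq_len(folds)) {
      te <- fold_id == f
      if (all(te) || length(unique(y[!te])) < 2) next
      m <- train_svm(X[!te, , drop = FALSE], y[!te], cost_c = cc)
      correct <- correct + sum(predict(m, X[te, , drop = FALSE]) ==
                                 as.character(y[te]))
    }
    correct / n
  }, 0)
  best <- grid[order(-acc, grid)][1]  # max accuracy, ties -> smallest C
  structure(best, cv_accuracy = stats::setNames(acc, grid))
}

#' Two-class confusion table with derived metrics
#'
#' @param tp,fn,tn,fp non-negative counts: true positives, false negatives,
#'   true negatives, false positives (cases are the positive class).
#' @return An object of class \code{confusion_table} with components
#'   \code{tp}, \code{fn}, \code{tn}, \code{fp}, \code{accuracy},
#'   \code{sensitivity}, \code{specificity}.
#' @examples
#' confusion_table(tp = 17, fn = 3, tn = 19, fp = 1)
#' @export
confusion_table <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 accuracy = if (total > 0) (tp + tn) / total else NA_real_,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table>\n")
  cat(sprintf("            predicted case  predicted control\n"))
  cat(sprintf("  case      %14d  %17d\n", x$tp, x$fn))
  cat(sprintf("  control   %14d  %17d\n", x$fp, x$tn))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
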