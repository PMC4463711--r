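#' Bayes (linear) discriminant analysis of KBD degree
#'
#' Gaussian linear discriminant with pooled within-class covariance,
#' classifying disease degree I vs II from the log2 expression ratios of the
#' signature genes. Class means are the per-class feature means; the pooled
#' covariance uses denominator (n - k); if the covariance is
#' ill-conditioned, a ridge term proportional to the mean diagonal is added
#' (escalated tenfold until the Cholesky factorization succeeds) and
#' recorded on the fit.
#'
#' @param X cases x genes numeric matrix (log2 ratios of the signature
#'   genes).
#' @param degrees per-case degree labels in \{"I", "II"\} (both present,
#'   >= 2 cases each).
#' @param priors \code{"equal"} (default, matching a balanced design) or
#'   \code{"proportional"} (class frequencies).
#' @return An object of class \code{bda}: \code{class_means},
#'   \code{pooled_covariance}, \code{priors}, \code{classes},
#'   \code{lambda} (ridge actually applied, 0 if none).
#' @export
fit_bda <- function(X, degrees, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("`X` must be finite")
  degrees <- factor(degrees)
  classes <- levels(degrees)
  if (length(classes) < 2) stop("a degree class is absent")
  counts <- table(degrees)
  if (any(counts < 2)) stop("need >= 2 cases per degree class")
  p <- ncol(X)
  mus <- do.call(rbind, lapply(classes, function(k)
    colMeans(X[degrees == k, , drop = FALSE])))
  rownames(mus) <- classes
  n <- nrow(X)
  k <- length(classes)
  S <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- X[degrees == cl, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    S <- S + crossprod(Xi)
  }
  S <- S / (n - k)
  lambda <- 0
  repeat {
    ch <- tryCatch(chol(S + diag(lambda, p)), error = function(e) NULL)
    if (!is.null(ch) && rcond(S + diag(lambda, p)) > 1e-12) break
    lambda <- if (lambda == 0) max(1e-6 * mean(diag(S)), 1e-8) else lambda * 10
    if (!is.finite(lambda) || lambda > 1e6 * max(mean(diag(S)), 1))
      stop("covariance regularization failed")
  }
  if (lambda > 0) S <- S + diag(lambda, p)
  pr <- if (priors == "equal") rep(1 / k, k) else as.numeric(counts) / n
  structure(list(class_means = mus, pooled_covariance = S,
                 priors = stats::setNames(pr, classes), classes = classes,
                 genes = colnames(X), lambda = lambda),
            class = "bda")
}

#' @export
print.bda <- function(x, ...) {
  cat(sprintf("<bda> %d-gene linear discriminant, classes %s, priors %s\n",
              ncol(x$class_means), paste(x$classes, collapse = "/"),
              paste(sprintf("%.2f", x$priors), collapse = "/")))
  if (x$lambda > 0) cat(sprintf("  ridge lambda = %.3g\n", x$lambda))
  invisible(x)
}

#' Classify cases with a fitted Bayes discriminant
#'
#' Assigns each observation to the class maximizing Gaussian density times
#' prior (shared pooled covariance), returning normalized posteriors. Exact
#' ties deterministically resolve to the first class (degree I).
#'
#' @param object a \code{\link{fit_bda}} model.
#' @param newdata vector (one case) or cases x genes matrix matching the
#'   model's genes.
#' @param ... unused.
#' @return List with \code{class} (character vector) and \code{posterior}
#'   (cases x classes matrix, rows summing to 1).
#' @export
predict.bda <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$genes) &&
      all(object$genes %in% colnames(X)))
    X <- X[, object$genes, drop = FALSE]
  if (ncol(X) != ncol(object$class_means))
    stop(sprintf("expected %d features, got %d", ncol(object$class_means),
                 ncol(X)))
  Sinv <- chol2inv(chol(object$pooled_covariance))
  # log discriminant: -(x - mu)' Sinv (x - mu)/2 + log prior
  disc <- vapply(seq_along(object$classes), function(j) {
    d <- sweep(X, 2, object$class_means[j, ])
    -0.5 * rowSums((d %*% Sinv) * d) + log(object$priors[j])
  }, numeric(nrow(X)))
  disc <- matrix(disc, nrow = nrow(X))
  m <- apply(disc, 1, max)
  post <- exp(disc - m)
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  cls <- object$classes[max.col(post, ties.method = "first")]
  list(class = cls, posterior = post)
}

#' Resubstitution and leave-one-out confusion tables for degree BDA
#'
#' The "original" table refits nothing: the model is fit on all cases and
#' classifies all cases. The cross-validated table refits the discriminant
#' with each case left out in turn and classifies that case with the
#' functions derived from all other cases.
#'
#' @inheritParams fit_bda
#' @return An object of class \code{bda_cv}: \code{original} and
#'   \code{cross_validated}, each a classes x classes count matrix
#'   (diagnosed in rows, predicted in columns), plus overall percent-correct
#'   figures.
#' @export
loocv_bda <- function(X, degrees, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  degrees <- factor(degrees)
  fit <- fit_bda(X, degrees, priors = priors)
  orig_pred <- predict(fit, X)$class
  n <- nrow(X)
  cv_pred <- vapply(seq_len(n), function(i) {
    m <- fit_bda(X[-i, , drop = FALSE], degrees[-i], priors = priors)
    predict(m, X[i, , drop = FALSE])$class
  }, "")
  tab <- function(pred) {
    t <- table(diagnosed = degrees, predicted = factor(pred,
                                                       levels = levels(degrees)))
    unclass(t)
  }
  orig <- tab(orig_pred)
  cv <- tab(cv_pred)
  structure(list(original = orig, cross_validated = cv,
                 pct_original = 100 * sum(diag(orig)) / sum(orig),
                 pct_cross_validated = 100 * sum(diag(cv)) / sum(cv)),
            class = "bda_cv")
}

#' @export
print.bda_cv <- function(x, ...) {
  block <- function(m, label) {
    classes <- rownames(m)
    cat(sprintf("%-16s %-6s %-10s %s  Total\n", label, "", "",
                paste(sprintf("Degree %-4s", classes), collapse = " ")))
    for (i in seq_along(classes)) {
      cat(sprintf("%-16s %-6s Degree %-3s %s  %5d\n",
                  "", "Count", classes[i],
                  paste(sprintf("%10d", m[i, ]), collapse = " "),
                  sum(m[i, ])))
    }
    for (i in seq_along(classes)) {
      pct <- 100 * m[i, ] / sum(m[i, ])
      cat(sprintf("%-16s %-6s Degree %-3s %s  %5.1f\n", "", "%", classes[i],
                  paste(sprintf("%10.1f", pct), collapse = " "), 100))
    }
  }
  cat("Bayes discriminant analysis: predicted group membership\n")
  block(x$original, "Original")
  block(x$cross_validated, "Cross-validated")
  cat(sprintf("%.1f%% of original grouped cases correctly classified\n",
              x$pct_original))
  cat(sprintf("%.1f%% of cross-validated grouped cases correctly classified\n",
              x$pct_cross_validated))
  invisible(x)
}

#' Overall percent correct of a square confusion count matrix
#'
#' @param counts square matrix of counts, true classes in rows and predicted
#'   classes in columns.
#' @return Percent of cases on the diagonal (0-100).
#' @examples
#' degree_accuracy(matrix(c(46, 5, 4, 45), 2))  # 91
#' @export
degree_accuracy <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("`counts` must be square")
  100 * sum(diag(counts)) / sum(counts)
}
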