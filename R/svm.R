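## Linear maximum-margin classification. The quadratic program is solved by
## libsvm (via e1071); this file owns the surrounding contract: explicit
## weight-vector/bias extraction with a pinned class orientation, decision
## values w.x + b, and nested cross-validated selection of the penalty C.

#' Fit a linear soft-margin support-vector classifier
#'
#' Solves the usual hinge-loss problem
#' `min 1/2 ||w||^2 + C sum_i max(0, 1 - y_i (w.x_i + b))`
#' with a linear kernel and returns the explicit hyperplane. Deterministic
#' for fixed input. Features are not rescaled: gray-matter probabilities
#' already share a common `[0, 1]` scale (optional per-feature
#' standardization, fit on the training data, via `standardize = TRUE`).
#'
#' @param x Numeric feature matrix, one row per subject.
#' @param y Class labels (two distinct values). If a factor, its levels fix
#'   the (negative, positive) order; otherwise sorted unique values do.
#' @param C Positive penalty parameter (default 1).
#' @param standardize Standardize columns to training mean 0 / SD 1.
#' @param tolerance Solver termination tolerance (default `1e-6`).
#' @return Object of class `linsvm`: `weights`, `bias`, `C`,
#'   `class_labels` (negative, positive), and any standardization
#'   parameters.
#' @seealso [decision_values()], [select_C()]
#' @export
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' m <- linsvm(x, c("a", "b"), C = 100)
#' coef(m)                       # weight ~1, bias ~0
linsvm <- function(x, y, C = 1, standardize = FALSE, tolerance = 1e-6) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite")
  if (!is.factor(y)) y <- factor(y, levels = sort(unique(as.character(y))))
  y <- droplevels(y)
  if (nlevels(y) != 2L)
    stop("need exactly two classes with >= 1 example each")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be > 0")
  ctr <- NULL; scl <- NULL
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  }
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = tolerance,
                    fitted = TRUE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## libsvm orients the decision function toward whichever class it met
  ## first; re-orient so the SECOND factor level is the positive class
  s <- libsvm_orientation(as.numeric(x %*% w + b), fit$fitted, levels(y))
  w <- s * w; b <- s * b
  structure(list(weights = w, bias = b, C = C,
                 class_labels = levels(y),
                 center = ctr, scale = scl,
                 n_support = nrow(fit$SV), n_train = nrow(x)),
            class = "linsvm")
}

## +1 if libsvm's decision function already points toward levels[2],
## -1 if it must be flipped; decided from the fitted training labels at the
## training point with the largest |decision value|
libsvm_orientation <- function(dv_tr, fitted, levels) {
  i <- which.max(abs(dv_tr))
  if (length(i) == 0L || dv_tr[i] == 0) return(1)
  pred_is_pos <- as.character(fitted[i]) == levels[2L]
  if (xor(dv_tr[i] > 0, pred_is_pos)) -1 else 1
}

## libsvm fit in Gram space: with a linear kernel the dual depends on the
## training data only through G = X X^T, so training on any factor Z with
## Z Z^T = G yields the identical solution while each kernel evaluation
## costs O(n) instead of O(p). Used by the cross-validation loops, where
## the same Gram matrix is reused across many folds.
gram_factor <- function(G) {
  R <- suppressWarnings(chol(G, pivot = TRUE))
  piv <- attr(R, "pivot")
  rank <- attr(R, "rank")
  Z <- matrix(0, nrow(G), rank)
  Z[piv, ] <- t(R[seq_len(rank), , drop = FALSE])
  Z
}

## returns a closure giving decision values for kernel columns
## k = <x_train_i, x_test_j> (a matrix n_train x n_test), oriented so the
## second level of y is positive
gram_linsvm <- function(G_tr, y_tr, C, tolerance = 1e-6) {
  Z <- gram_factor(G_tr)
  fit <- e1071::svm(Z, y_tr, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = tolerance,
                    fitted = TRUE)
  coefs <- as.numeric(fit$coefs)
  idx <- fit$index
  dv_tr <- as.numeric(crossprod(G_tr[idx, , drop = FALSE], coefs)) - fit$rho
  s <- libsvm_orientation(dv_tr, fit$fitted, levels(y_tr))
  function(k_cross) {
    s * (as.numeric(crossprod(k_cross[idx, , drop = FALSE], coefs)) - fit$rho)
  }
}

## inner-CV C selection working on a precomputed Gram matrix
select_C_gram <- function(G, y, c_grid, inner_folds, seed) {
  if (length(c_grid) == 1L) return(c_grid)
  if (min(table(y)) < inner_folds)
    stop("inner_folds exceeds the smaller class size")
  fold <- stratified_folds(y, inner_folds, seed)
  balacc <- numeric(length(c_grid))
  for (ci in seq_along(c_grid)) {
    accs <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      dvf <- gram_linsvm(G[tr, tr, drop = FALSE], droplevels(y[tr]),
                         C = c_grid[ci])
      dv <- dvf(G[tr, te, drop = FALSE])
      pred <- ifelse(dv >= 0, levels(y)[2L], levels(y)[1L])
      ytest <- as.character(y[te])
      per_class <- vapply(levels(y), function(cl) {
        n <- sum(ytest == cl)
        if (n == 0L) NA_real_ else sum(pred == cl & ytest == cl) / n
      }, numeric(1L))
      accs[f] <- mean(per_class, na.rm = TRUE)
    }
    balacc[ci] <- mean(accs)
  }
  c_grid[which.max(balacc)]
}

#' Signed decision values of a fitted linear classifier
#'
#' Returns `w . x + b` per subject (on the model's standardized scale if the
#' model was standardized). The predicted class is the sign; a decision
#' value of exactly zero predicts the positive class.
#'
#' @param model A [linsvm()] fit.
#' @param x Feature matrix with `length(model$weights)` columns.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "linsvm"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$weights))
    stop(sprintf("feature count %d does not match model (%d)",
                 ncol(x), length(model$weights)))
  if (!is.null(model$center))
    x <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  as.numeric(x %*% model$weights + model$bias)
}

#' @export
predict.linsvm <- function(object, newdata, type = c("class", "decision"),
                           ...) {
  type <- match.arg(type)
  dv <- decision_values(object, newdata)
  if (type == "decision") return(dv)
  ifelse(dv >= 0, object$class_labels[2L], object$class_labels[1L])
}

#' @export
coef.linsvm <- function(object, ...) {
  c(bias = object$bias, setNames(object$weights,
                                 paste0("w", seq_along(object$weights))))
}

#' @export
print.linsvm <- function(x, ...) {
  cat(sprintf(
    "Linear SVM: %d features, C = %g, %d/%d support vectors\n  classes: %s (-) vs %s (+)\n",
    length(x$weights), x$C, x$n_support, x$n_train,
    x$class_labels[1L], x$class_labels[2L]))
  invisible(x)
}

## stratified fold assignment: within each class, shuffle then deal round-robin
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Select the penalty C by inner stratified cross-validation
#'
#' Evaluates each candidate C by `inner_folds`-fold stratified
#' cross-validation on the training set and returns the value maximizing
#' mean balanced accuracy (mean of the two per-class accuracies); ties break
#' toward the smallest C, favouring the larger margin. With a single
#' candidate no folds are computed.
#'
#' @param x Training feature matrix.
#' @param y Training labels (two classes).
#' @param c_grid Strictly increasing vector of positive candidates (default
#'   `10^(-3:3)`).
#' @param inner_folds Number of inner folds (default 5; capped at the
#'   smaller class size must hold).
#' @param seed Seed for the fold assignment.
#' @return The selected C (a single positive number).
#' @export
select_C <- function(x, y, c_grid = 10^(-3:3), inner_folds = 5L, seed = 1L) {
  if (length(c_grid) == 0L || any(c_grid <= 0) || is.unsorted(c_grid,
                                                              strictly = TRUE))
    stop("c_grid must be a nonempty strictly increasing positive vector")
  if (length(c_grid) == 1L) return(c_grid)
  if (!is.factor(y)) y <- factor(y, levels = sort(unique(as.character(y))))
  x <- as.matrix(x)
  ## which.max inside takes the first maximum; the grid is increasing, so
  ## ties break toward the smallest C
  select_C_gram(tcrossprod(x), y, c_grid, inner_folds, seed)
}
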