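# Linear SVM built on the package's dual coordinate descent solver.
#
# The solver works from the Gram matrix of the (optionally standardized,
# bias-augmented) training rows, which makes label-permutation loops cheap:
# the Gram matrix is computed once per fold and reused for every permuted
# label vector.

# Standardize columns with training statistics; zero-variance columns are
# set to 0 and flagged.
standardize_train <- function(X) {
  mu <- colMeans(X)
  sds <- matrixStats::colSds(X)
  degenerate <- sds == 0 | !is.finite(sds)
  sds[degenerate] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  Xs[, degenerate] <- 0
  list(X = Xs, mean = mu, sd = sds, degenerate = degenerate)
}

#' Train a linear support vector machine
#'
#' L2-regularized hinge-loss linear SVM solved by deterministic dual
#' coordinate descent; the bias is handled by Gram-matrix augmentation
#' (equivalent to a regularized intercept feature of 1). Features may be
#' standardized with training-set statistics (default), which is how the
#' decoding and selection modules call it.
#'
#' @param X Numeric matrix, rows = samples, columns = features.
#' @param y Labels: a factor with two levels, or a +-1 numeric vector. The
#'   first factor level maps to +1.
#' @param C Soft-margin cost (default 1).
#' @param standardize Standardize columns with training statistics.
#' @param max_iter Maximum coordinate-descent epochs.
#' @param tol Projected-gradient stopping tolerance.
#' @return An object of class `svm_linear` with weights `w` (on the input
#'   feature scale when `standardize = FALSE`, otherwise on the standardized
#'   scale), bias `b`, dual variables `alpha`, and the scaling parameters.
#' @export
svm_linear <- function(X, y, C = 1, standardize = TRUE, max_iter = 500L,
                       tol = 1e-6) {
  X <- as.matrix(X)
  yv <- svm_labels(y)
  if (length(unique(yv)) < 2) stop_sl("svm_linear: both classes required")
  sc <- if (standardize) standardize_train(X) else
    list(X = X, mean = rep(0, ncol(X)), sd = rep(1, ncol(X)),
         degenerate = rep(FALSE, ncol(X)))
  K <- tcrossprod(sc$X) + 1
  alpha <- dcd_svm_alpha(K, as.integer(yv), C, as.integer(max_iter), tol)
  coefs <- alpha * yv
  structure(list(w = drop(crossprod(sc$X, coefs)), b = sum(coefs),
                 alpha = alpha, C = C, standardize = standardize,
                 center = sc$mean, scale = sc$sd,
                 degenerate = sc$degenerate,
                 levels = if (is.factor(y)) levels(y) else NULL),
            class = "svm_linear")
}

svm_labels <- function(y) {
  if (is.factor(y)) {
    stopifnot(nlevels(y) == 2)
    ifelse(as.integer(y) == 1L, 1, -1)
  } else {
    stopifnot(all(y %in% c(-1, 1)))
    as.numeric(y)
  }
}

#' @export
predict.svm_linear <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (object$standardize) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
    X[, object$degenerate] <- 0
  }
  score <- drop(X %*% object$w) + object$b
  cls <- ifelse(score >= 0, 1, -1)
  if (!is.null(object$levels)) {
    factor(object$levels[ifelse(cls == 1, 1L, 2L)], levels = object$levels)
  } else {
    cls
  }
}
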