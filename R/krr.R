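#' Kinship-profile feature matrix
#'
#' The feature vector of an individual is its row of the joint GRM restricted
#' to the training columns (its relationship profile to the training set), so
#' feature dimension equals the training size regardless of marker count —
#' the dimensionality-reduction device used by all five ML regressors here.
#'
#' @param grmJoint joint train-plus-query \linkS4class{GRMatrix}.
#' @param trainIds ids defining the feature columns (fixed order).
#' @param queryIds ids of the rows to extract.
#' @return numeric matrix, length(queryIds) x length(trainIds), dimnames set.
#' @export
makeGrmFeatures <- function(grmJoint, trainIds, queryIds) {
  stopifnot(is(grmJoint, "GRMatrix"))
  ids <- sampleIds(grmJoint)
  ri <- match(queryIds, ids)
  ci <- match(trainIds, ids)
  if (anyNA(ri) || anyNA(ci)) stop("unknown id(s) in the joint GRM")
  out <- grmValues(grmJoint)[ri, ci, drop = FALSE]
  dimnames(out) <- list(queryIds, trainIds)
  out
}

#' Radial-basis-function kernel between feature rows
#'
#' @param X1,X2 feature matrices (rows are samples).
#' @param gamma RBF bandwidth: K = exp(-gamma * squared distance).
#' @return kernel matrix nrow(X1) x nrow(X2).
#' @export
rbfKernel <- function(X1, X2 = X1, gamma = 1 / ncol(X1)) {
  s1 <- rowSums(X1^2)
  s2 <- rowSums(X2^2)
  d2 <- outer(s1, s2, "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit kernel ridge regression
#'
#' Dual solution of ridge regression in kernel space: predictions for a test
#' sample are k' (K + lambda I)^-1 y, with k' the row of kernel evaluations
#' against the training samples. Two kernels are supported: "linear"
#' treats the supplied matrix as the (precomputed) kernel — e.g. the GRM
#' itself — and "rbf" builds a Gaussian kernel from feature rows.
#'
#' @param K training kernel matrix (kernel = "linear") or feature matrix
#'   (kernel = "rbf").
#' @param y training targets.
#' @param lambda positive regularization constant.
#' @param kernel "linear" or "rbf".
#' @param gamma RBF bandwidth (kernel = "rbf").
#' @return object of class \code{krrFit}: dual coefficients, kernel spec,
#'   training features (rbf only).
#' @export
fitKrr <- function(K, y, lambda, kernel = c("linear", "rbf"),
                   gamma = NULL) {
  kernel <- match.arg(kernel)
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  K <- as.matrix(K)
  Xtrain <- NULL
  if (kernel == "rbf") {
    if (is.null(gamma)) gamma <- 1 / ncol(K)
    Xtrain <- K
    K <- rbfKernel(Xtrain, Xtrain, gamma)
  }
  n <- nrow(K)
  if (ncol(K) != n || length(y) != n)
    stop("K must be square and match y")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("kernel matrix must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev)))
    stop("kernel matrix is not PSD within tolerance")
  dual <- solve(K + diag(lambda, n), y)
  structure(list(dual = dual, lambda = lambda, kernel = kernel,
                 gamma = gamma, Xtrain = Xtrain, n = n),
            class = "krrFit")
}

#' Predict from a kernel ridge fit
#'
#' @param object a \code{krrFit}.
#' @param newdata for the linear kernel: matrix of kernel rows k'
#'   (n_new x n_train, e.g. the G\[test, train\] block); for the RBF kernel:
#'   new feature rows.
#' @param ... unused.
#' @return numeric predictions k' (K + lambda I)^-1 y.
#' @export
predict.krrFit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  kRows <- if (object$kernel == "rbf")
    rbfKernel(newdata, object$Xtrain, object$gamma) else newdata
  if (ncol(kRows) != object$n)
    stop("kernel rows must have one column per training sample")
  as.numeric(kRows %*% object$dual)
}

#' @export
print.krrFit <- function(x, ...) {
  cat("krrFit:", x$n, "training samples,", x$kernel, "kernel, lambda =",
      signif(x$lambda, 4), "\n")
  invisible(x)
}
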