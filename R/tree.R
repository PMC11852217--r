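#' Fit a CART regression tree
#'
#' Greedy variance-reduction splits over exact candidate thresholds (the
#' midpoints of sorted distinct feature values), with optional sample weights
#' and per-split feature subsampling. Deterministic given seed and feature
#' order; a constant target yields a single-leaf tree predicting that
#' constant. An optional quantile pre-binning mode ("histogram" splits)
#' trades exactness for speed on large feature sets.
#'
#' @param X feature matrix (samples x features).
#' @param y numeric targets.
#' @param maxDepth maximum tree depth (root = depth 0; default 6).
#' @param minLeaf minimum samples per leaf (default 5).
#' @param weights optional non-negative sample weights.
#' @param mtryFrac fraction of features considered at each split
#'   (default 1 = all; no RNG is consumed at 1).
#' @param nBins 0 for exact thresholds; a positive value pre-bins each
#'   feature to that many quantile bins.
#' @return object of class \code{cartTree} (flat node arrays).
#' @export
fitTree <- function(X, y, maxDepth = 6, minLeaf = 5, weights = NULL,
                    mtryFrac = 1, nBins = 0) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (length(y) != n) stop("X rows must match y")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be non-negative, one per sample")
  if (n < 2 * minLeaf && n > 1) {
    # too small to split: root leaf
    maxDepth <- 0
  }
  if (nBins > 0) X <- binFeatures(X, nBins)
  mtry <- max(1L, ceiling(mtryFrac * ncol(X)))
  tr <- cart_fit_cpp(X, as.numeric(y), as.numeric(weights),
                     as.integer(maxDepth), as.integer(minLeaf),
                     as.integer(mtry))
  structure(c(tr, list(p = ncol(X), maxDepth = maxDepth,
                       nBins = nBins)), class = "cartTree")
}

binFeatures <- function(X, nBins) {
  apply(X, 2, function(v) {
    qs <- unique(quantile(v, probs = seq(0, 1, length.out = nBins + 1),
                          names = FALSE, type = 7))
    if (length(qs) < 3) return(v)
    mids <- (qs[-1] + qs[-length(qs)]) / 2
    mids[pmin(pmax(findInterval(v, qs, rightmost.closed = TRUE), 1),
              length(mids))]
  })
}

#' Predict from a CART tree
#'
#' @param object a \code{cartTree}.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return numeric leaf predictions.
#' @export
predict.cartTree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$p) stop("feature count mismatch")
  cart_predict_cpp(object$feature, object$threshold, object$left,
                   object$right, object$value, newdata)
}

#' @export
print.cartTree <- function(x, ...) {
  cat("cartTree:", sum(x$feature < 0), "leaves,",
      length(x$feature), "nodes\n")
  invisible(x)
}
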