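#' Fit a random forest of CART trees
#'
#' Bootstrap-bagged trees with per-split feature subsampling; the forest
#' prediction is the plain arithmetic mean of member-tree predictions. With
#' one tree, bagging off and all features considered, the forest reduces
#' exactly to \code{\link{fitTree}}.
#'
#' @param X feature matrix.
#' @param y numeric targets.
#' @param nTrees number of trees (default 200).
#' @param maxDepth,minLeaf,nBins passed to \code{\link{fitTree}}.
#' @param mtryFrac per-split feature fraction (default 1/3).
#' @param bag bootstrap-resample rows for each tree? (default TRUE)
#' @param seed integer seed.
#' @return object of class \code{rfFit} holding the member trees.
#' @export
fitRf <- function(X, y, nTrees = 200, maxDepth = 8, minLeaf = 5,
                  mtryFrac = 1 / 3, bag = TRUE, nBins = 0, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (nTrees < 1) stop("nTrees must be >= 1")
  set.seed(seed)
  trees <- vector("list", nTrees)
  for (m in seq_len(nTrees)) {
    idx <- if (bag) sample.int(n, n, replace = TRUE) else seq_len(n)
    trees[[m]] <- fitTree(X[idx, , drop = FALSE], y[idx],
                          maxDepth = maxDepth, minLeaf = minLeaf,
                          mtryFrac = mtryFrac, nBins = nBins)
  }
  structure(list(trees = trees, p = ncol(X), seed = seed),
            class = "rfFit")
}

#' Predict from a random forest
#'
#' @param object an \code{rfFit}.
#' @param newdata feature matrix.
#' @param individual return the member-tree prediction matrix instead of
#'   the mean?
#' @param ... unused.
#' @return mean prediction vector (or n x M matrix when
#'   \code{individual = TRUE}).
#' @export
predict.rfFit <- function(object, newdata, individual = FALSE, ...) {
  preds <- vapply(object$trees, predict, numeric(nrow(as.matrix(newdata))),
                  newdata = newdata)
  preds <- matrix(preds, nrow = nrow(as.matrix(newdata)))
  if (individual) preds else rowMeans(preds)
}

#' Fit gradient-boosted regression trees (optionally with GOSS)
#'
#' Stagewise least-squares boosting: the base model predicts mean(y); each
#' stage fits a tree to the current residuals and adds it with shrinkage
#' \code{learningRate}. The GOSS variant (gradient-based one-side sampling)
#' keeps the top \code{gossA} fraction of samples by absolute residual,
#' samples a random \code{gossB} fraction of the remainder, and upweights the
#' sampled remainder by (1 - gossA)/gossB; with gossA = 1 no sampling (and no
#' RNG) happens and the fit is bit-identical to plain GBDT.
#'
#' @param X feature matrix.
#' @param y numeric targets.
#' @param nTrees number of boosting stages M (0 gives the mean-only model).
#' @param learningRate shrinkage in (0, 1\].
#' @param maxDepth,minLeaf,nBins tree controls.
#' @param gossA top-gradient keep fraction (1 = GOSS off).
#' @param gossB random-sample fraction of the remainder.
#' @param seed integer seed.
#' @return object of class \code{gbdtFit}: f0, trees, learningRate.
#' @export
fitGbdt <- function(X, y, nTrees = 100, learningRate = 0.1, maxDepth = 3,
                    minLeaf = 5, gossA = 1, gossB = 0.1, nBins = 0,
                    seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (learningRate <= 0 || learningRate > 1)
    stop("learningRate must be in (0, 1]")
  if (gossA <= 0 || gossA > 1 || gossB <= 0 || gossB > 1)
    stop("GOSS fractions must be in (0, 1]")
  set.seed(seed)
  f0 <- mean(y)
  pred <- rep(f0, n)
  trees <- vector("list", nTrees)
  m <- 0L
  while (m < nTrees) {
    m <- m + 1L
    r <- y - pred
    if (gossA < 1) {
      na <- ceiling(gossA * n)
      ord <- order(abs(r), decreasing = TRUE)
      top <- ord[seq_len(na)]
      rest <- ord[-seq_len(na)]
      nb <- min(length(rest), ceiling(gossB * n))
      samp <- if (nb > 0) sample(rest, nb) else integer()
      idx <- c(top, samp)
      w <- c(rep(1, na), rep((1 - gossA) / gossB, length(samp)))
      tr <- fitTree(X[idx, , drop = FALSE], r[idx], maxDepth = maxDepth,
                    minLeaf = minLeaf, weights = w, nBins = nBins)
    } else {
      tr <- fitTree(X, r, maxDepth = maxDepth, minLeaf = minLeaf,
                    nBins = nBins)
    }
    trees[[m]] <- tr
    pred <- pred + learningRate * predict(tr, X)
  }
  structure(list(f0 = f0, trees = trees, learningRate = learningRate,
                 p = ncol(X), seed = seed), class = "gbdtFit")
}

#' Predict from a gradient-boosted ensemble
#'
#' @param object a \code{gbdtFit}.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return f0 + learningRate * sum of stage-tree predictions.
#' @export
predict.gbdtFit <- function(object, newdata, ...) {
  out <- rep(object$f0, nrow(as.matrix(newdata)))
  for (tr in object$trees)
    out <- out + object$learningRate * predict(tr, newdata)
  out
}

#' Fit AdaBoost.R2 with CART base learners
#'
#' Drucker-style boosting for regression: per-round sample losses are
#' normalized to \[0, 1\] by the chosen loss, the round's error rate is the
#' weight-averaged loss Lbar with epsilon = Lbar / (1 - Lbar), and sample
#' weights update multiplicatively by epsilon^(lr * (1 - L_i)). Boosting
#' stops when a round's Lbar reaches 0.5; if the very first learner does, it
#' is kept alone with a warning. Prediction is the weighted median of the
#' weak predictions with weights lr * log(1/epsilon) — the smallest
#' prediction whose cumulative weight reaches half the total (infimum
#' semantics).
#'
#' @param X feature matrix.
#' @param y numeric targets.
#' @param nTrees maximum rounds.
#' @param loss "linear", "square" or "exponential".
#' @param learningRate shrinkage exponent in (0, 1\].
#' @param maxDepth,minLeaf,nBins tree controls.
#' @param seed integer seed (weighted resampling-free; weights enter the
#'   tree fit directly).
#' @return object of class \code{adaboostFit}: trees, modelWeights,
#'   epsilons, loss.
#' @export
fitAdaboostR2 <- function(X, y, nTrees = 50,
                          loss = c("linear", "square", "exponential"),
                          learningRate = 1, maxDepth = 4, minLeaf = 5,
                          nBins = 0, seed = 1L) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  n <- nrow(X)
  if (learningRate <= 0 || learningRate > 1)
    stop("learningRate must be in (0, 1]")
  set.seed(seed)
  D <- rep(1 / n, n)
  trees <- list()
  wts <- numeric()
  eps <- numeric()
  for (t in seq_len(nTrees)) {
    tr <- fitTree(X, y, maxDepth = maxDepth, minLeaf = minLeaf,
                  weights = D, nBins = nBins)
    ft <- predict(tr, X)
    err <- abs(ft - y)
    emax <- max(err)
    L <- if (emax <= 0) rep(0, n) else switch(loss,
      linear = err / emax,
      square = (err / emax)^2,
      exponential = 1 - exp(-err / emax))
    Lbar <- sum(D * L)
    if (Lbar >= 0.5) {
      if (t == 1L) {
        warning("first learner has average loss >= 0.5; single-learner fit")
        trees <- list(tr)
        wts <- 1
        eps <- Lbar / (1 - Lbar + 1e-12)
      }
      break
    }
    e <- max(Lbar / (1 - Lbar), 1e-12)
    trees[[t]] <- tr
    eps[t] <- e
    wts[t] <- learningRate * log(1 / e)
    D <- D * e^(learningRate * (1 - L))
    D <- D / sum(D)
  }
  if (!length(trees)) stop("no learners fitted")
  structure(list(trees = trees, modelWeights = wts, epsilons = eps,
                 loss = loss, p = ncol(X), seed = seed),
            class = "adaboostFit")
}

#' Weighted-median prediction from an AdaBoost.R2 ensemble
#'
#' @param object an \code{adaboostFit}.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return weighted-median predictions.
#' @export
predict.adaboostFit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  P <- vapply(object$trees, predict, numeric(nrow(newdata)),
              newdata = newdata)
  P <- matrix(P, nrow = nrow(newdata))
  w <- object$modelWeights
  apply(P, 1, weightedMedian, w = w)
}

# smallest value whose cumulative weight reaches half the total
weightedMedian <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= cw[length(cw)] / 2)[1]]
}

#' @export
print.rfFit <- function(x, ...) {
  cat("rfFit:", length(x$trees), "trees\n")
  invisible(x)
}

#' @export
print.gbdtFit <- function(x, ...) {
  cat("gbdtFit:", length(x$trees), "stages, learning rate",
      x$learningRate, "\n")
  invisible(x)
}

#' @export
print.adaboostFit <- function(x, ...) {
  cat("adaboostFit:", length(x$trees), "rounds,", x$loss, "loss\n")
  invisible(x)
}
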