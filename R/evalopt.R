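#' Prediction accuracy: Pearson correlation
#'
#' r = cov(ypred, ytrue) / sqrt(var(ypred) var(ytrue)). Constant inputs have
#' no defined correlation; the function returns NA with a warning so callers
#' can exclude the fold from aggregation.
#'
#' @param ypred,ytrue equal-length numeric vectors (length >= 3).
#' @return Pearson r, or NA for a degenerate input.
#' @export
accuracy <- function(ypred, ytrue) {
  if (length(ypred) != length(ytrue)) stop("length mismatch")
  if (length(ypred) < 3) stop("need at least 3 pairs")
  if (sd(ypred) == 0 || sd(ytrue) == 0) {
    warning("constant vector: accuracy undefined")
    return(NA_real_)
  }
  cor(ypred, ytrue)
}

#' Fivefold (k-fold) cross-validation of a prediction method
#'
#' Individuals are shuffled under the seed and split into k near-equal,
#' disjoint folds. For each fold the supplied closure fits on the remaining
#' folds and predicts the held-out individuals; accuracy is computed per fold
#' and aggregated as the unweighted mean and SD across folds.
#'
#' @param y trait vector over the training population.
#' @param fitPredict function(trainIdx, testIdx) returning predictions for
#'   \code{testIdx} from a model fitted on \code{trainIdx}.
#' @param k number of folds (default 5).
#' @param seed partition seed.
#' @param method label stored in the report.
#' @return object of class \code{cvReport}: method, foldR, meanR, sdR,
#'   folds (the index partition), seed.
#' @export
kfoldCv <- function(y, fitPredict, k = 5, seed = 1L, method = "") {
  n <- length(y)
  if (k < 2 || n < k) stop("need k >= 2 and n >= k")
  set.seed(seed)
  perm <- sample.int(n)
  folds <- unname(split(perm, cut(seq_len(n), k, labels = FALSE)))
  foldR <- vapply(folds, function(test) {
    train <- setdiff(seq_len(n), test)
    pred <- fitPredict(train, test)
    if (sd(y[test]) == 0) return(NA_real_)
    accuracy(pred, y[test])
  }, numeric(1))
  ok <- !is.na(foldR)
  structure(list(method = method, foldR = foldR, meanR = mean(foldR[ok]),
                 sdR = sd(foldR[ok]), folds = folds, seed = seed),
            class = "cvReport")
}

#' @export
print.cvReport <- function(x, ...) {
  cat("cvReport", if (nzchar(x$method)) paste0("[", x$method, "]") else "",
      ": mean r =", signif(x$meanR, 4), "+/-", signif(x$sdR, 4), "over",
      length(x$foldR), "folds\n")
  invisible(x)
}

#' Bayesian hyperparameter optimization (GP surrogate, expected improvement)
#'
#' Maximizes a black-box objective over a bounded space. A Gaussian-process
#' surrogate with a Matern-5/2 kernel is fitted on inputs normalized to the
#' unit cube (categorical dimensions via one-of-k indicators); each
#' iteration evaluates the point maximizing expected improvement over a
#' random candidate set. Non-finite objective values are recorded as
#' failures and never proposed as the best. Same seed, same evaluation
#' sequence.
#'
#' @param objective function(params) -> scalar to maximize; params is a
#'   named list.
#' @param space named list of dimensions, each
#'   list(type = "num"|"int"|"cat", lower=, upper=, log=FALSE, values=).
#' @param nIter total objective evaluations (default 300, the paper-scale
#'   setting; desk runs use 30-50).
#' @param nInit random initial design size (default max(5, 2 * d)).
#' @param nCandidates acquisition candidate-set size.
#' @param seed integer seed.
#' @return object of class \code{tuneResult}: evaluated points with
#'   objective values, best parameters, best value, nIter.
#' @export
bayesOpt <- function(objective, space, nIter = 300, nInit = NULL,
                     nCandidates = 500, seed = 1L) {
  d <- length(space)
  if (!d) stop("empty search space")
  if (is.null(nInit)) nInit <- max(5L, 2L * d)
  nInit <- min(nInit, nIter)
  set.seed(seed)

  sampleUnit <- function(k) matrix(runif(k * d), k, d)
  toParams <- function(u) {
    params <- vector("list", d)
    names(params) <- names(space)
    for (j in seq_len(d)) {
      dim <- space[[j]]
      if (identical(dim$type, "cat")) {
        i <- pmin(floor(u[j] * length(dim$values)) + 1L, length(dim$values))
        params[[j]] <- dim$values[[i]]
      } else {
        lo <- dim$lower; hi <- dim$upper
        v <- if (isTRUE(dim$log))
          exp(log(lo) + u[j] * (log(hi) - log(lo)))
        else lo + u[j] * (hi - lo)
        if (identical(dim$type, "int")) v <- as.integer(round(v))
        params[[j]] <- v
      }
    }
    params
  }

  U <- sampleUnit(nInit)
  vals <- rep(NA_real_, nIter)
  paramList <- vector("list", nIter)
  for (i in seq_len(nInit)) {
    paramList[[i]] <- toParams(U[i, ])
    v <- suppressWarnings(objective(paramList[[i]]))
    vals[i] <- if (is.finite(v)) v else NA_real_
  }

  matern52 <- function(A, B, ell) {
    r <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") -
                     2 * tcrossprod(A, B), 0)) / ell
    (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }

  for (i in seq(nInit + 1L, length.out = nIter - nInit)) {
    ok <- which(is.finite(vals[seq_len(i - 1L)]))
    if (length(ok) < 3L) {
      u <- as.numeric(sampleUnit(1L))
    } else {
      Xo <- U[ok, , drop = FALSE]
      yo <- vals[ok]
      mu0 <- mean(yo)
      sdy <- sd(yo)
      if (!is.finite(sdy) || sdy == 0) sdy <- 1
      ys <- (yo - mu0) / sdy
      # marginal-likelihood fit of a single lengthscale (log scale)
      nll <- function(lel) {
        ell <- exp(lel)
        Km <- matern52(Xo, Xo, ell) + diag(1e-6 + 1e-4, length(ok))
        ch <- tryCatch(chol(Km), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
        a <- backsolve(ch, forwardsolve(t(ch), ys))
        sum(ys * a) / 2 + sum(log(diag(ch)))
      }
      ell <- exp(optim(log(0.3), nll, method = "Brent", lower = log(0.02),
                       upper = log(3))$par)
      Km <- matern52(Xo, Xo, ell) + diag(1e-6 + 1e-4, length(ok))
      ch <- chol(Km)
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      cand <- sampleUnit(nCandidates)
      Kc <- matern52(cand, Xo, ell)
      muc <- as.numeric(Kc %*% alpha)
      vsolve <- forwardsolve(t(ch), t(Kc))
      s2 <- pmax(1 - colSums(vsolve^2), 1e-12)
      sc <- sqrt(s2)
      best <- max(ys)
      z <- (muc - best) / sc
      ei <- sc * (z * pnorm(z) + dnorm(z))
      u <- cand[which.max(ei), ]
    }
    U <- rbind(U, u)
    paramList[[i]] <- toParams(u)
    v <- suppressWarnings(objective(paramList[[i]]))
    vals[i] <- if (is.finite(v)) v else NA_real_
  }

  okAll <- which(is.finite(vals))
  if (!length(okAll)) stop("objective never returned a finite value")
  bestI <- okAll[which.max(vals[okAll])]
  structure(list(points = paramList, values = vals,
                 best = paramList[[bestI]], bestValue = vals[bestI],
                 nIter = nIter, seed = seed), class = "tuneResult")
}

#' @export
print.tuneResult <- function(x, ...) {
  cat("tuneResult:", x$nIter, "evaluations, best objective",
      signif(x$bestValue, 4), "\n")
  invisible(x)
}

#' Independent-test accuracy with a leakage guard
#'
#' Computes the single holdout correlation between predictions and observed
#' values; hyperparameters must have been frozen beforehand (no refitting
#' here). Any id present in both the training and holdout sets aborts unless
#' explicitly allowed.
#'
#' @param ypred predictions for the holdout individuals.
#' @param ytrue observed holdout values.
#' @param trainIds,testIds id vectors used for the overlap guard (optional).
#' @param allowOverlap disable the guard (diagnostics only).
#' @return Pearson r on the holdout.
#' @export
independentTest <- function(ypred, ytrue, trainIds = NULL, testIds = NULL,
                            allowOverlap = FALSE) {
  if (!allowOverlap && !is.null(trainIds) && !is.null(testIds)) {
    ov <- intersect(trainIds, testIds)
    if (length(ov))
      stop("train/holdout id overlap (leakage): ",
           paste(head(ov, 5), collapse = ", "))
  }
  accuracy(ypred, ytrue)
}

#' Consistency between cross-validation and independent-test series
#'
#' Pearson correlation between the CV accuracy series and the
#' independent-test accuracy series across panel sizes, per method.
#'
#' @param cvSeries,indepSeries numeric vectors (one method) or matrices with
#'   one row per method, columns aligned over panel sizes.
#' @return named numeric vector of per-method correlations.
#' @export
consistency <- function(cvSeries, indepSeries) {
  if (is.null(dim(cvSeries))) {
    cvSeries <- matrix(cvSeries, 1)
    indepSeries <- matrix(indepSeries, 1)
  }
  if (!all(dim(cvSeries) == dim(indepSeries)))
    stop("series must be aligned")
  out <- vapply(seq_len(nrow(cvSeries)), function(i)
    cor(cvSeries[i, ], indepSeries[i, ]), numeric(1))
  names(out) <- rownames(cvSeries)
  out
}

#' One-way fixed-effects ANOVA across trait vectors
#'
#' Stacks the groups, runs the classical one-way analysis of variance, and
#' reports the full table including the critical F at \code{alpha}.
#'
#' @param traitVectors named list of numeric vectors (>= 2 groups, each
#'   n >= 2).
#' @param alpha level for the critical F (default 0.05).
#' @return an \code{anovaTable} (see \code{\link{anovaFromSummary}}).
#' @export
anovaAcrossTraits <- function(traitVectors, alpha = 0.05) {
  if (length(traitVectors) < 2) stop("need at least 2 groups")
  if (any(vapply(traitVectors, length, 1L) < 2))
    stop("each group needs n >= 2")
  df <- data.frame(
    value = unlist(traitVectors, use.names = FALSE),
    group = factor(rep(seq_along(traitVectors),
                       vapply(traitVectors, length, 1L))))
  wvar <- vapply(split(df$value, df$group), var, numeric(1))
  if (all(wvar == 0)) stop("zero within-group variance")
  tab <- anova(aov(value ~ group, data = df))
  anovaFromSummary(ssBetween = tab$`Sum Sq`[1], dfBetween = tab$Df[1],
                   ssWithin = tab$`Sum Sq`[2], dfWithin = tab$Df[2],
                   alpha = alpha)
}

#' Complete a one-way ANOVA table from sums of squares and df
#'
#' Derived quantities (mean squares, F, p, critical F, totals) recomputed
#' from the two primary sums of squares and their degrees of freedom — the
#' arithmetic a published ANOVA table must satisfy.
#'
#' @param ssBetween,dfBetween,ssWithin,dfWithin primary entries.
#' @param alpha level for the critical F (default 0.05).
#' @return list of class \code{anovaTable}: ssBetween, dfBetween, msBetween,
#'   F, p, fCrit, ssWithin, dfWithin, msWithin, ssTotal, dfTotal.
#' @export
anovaFromSummary <- function(ssBetween, dfBetween, ssWithin, dfWithin,
                             alpha = 0.05) {
  msB <- ssBetween / dfBetween
  msW <- ssWithin / dfWithin
  Fv <- msB / msW
  structure(list(ssBetween = ssBetween, dfBetween = dfBetween,
                 msBetween = msB, F = Fv,
                 p = pf(Fv, dfBetween, dfWithin, lower.tail = FALSE),
                 fCrit = qf(1 - alpha, dfBetween, dfWithin),
                 ssWithin = ssWithin, dfWithin = dfWithin, msWithin = msW,
                 ssTotal = ssBetween + ssWithin,
                 dfTotal = dfBetween + dfWithin), class = "anovaTable")
}

#' @export
print.anovaTable <- function(x, ...) {
  cat(sprintf("%-9s %12s %6s %12s %10s %12s %8s\n", "Source", "SS", "df",
              "MS", "F", "p", "F crit"))
  cat(sprintf("%-9s %12.3f %6d %12.3f %10.3f %12.3e %8.3f\n", "Between",
              x$ssBetween, x$dfBetween, x$msBetween, x$F, x$p, x$fCrit))
  cat(sprintf("%-9s %12.3f %6d %12.3f\n", "Within", x$ssWithin, x$dfWithin,
              x$msWithin))
  cat(sprintf("%-9s %12.3f %6d\n", "Total", x$ssTotal, x$dfTotal))
  invisible(x)
}
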