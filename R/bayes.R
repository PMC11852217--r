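#' Prior specification for the Bayesian alphabet
#'
#' One prior family per model: BRR (a common normal shrinkage variance),
#' Bayes A (per-locus scaled-inverse-chi-square variances with a gamma
#' hyperprior on the scale), Bayes B (spike-slab with per-locus slab
#' variances, beta prior on the inclusion probability, gamma hyperprior on
#' the scale), Bayes C (spike-slab with a common slab variance and beta prior
#' on inclusion), and BL (Bayesian LASSO: normal-exponential mixture with a
#' gamma hyperprior on lambda^2).
#'
#' Unset scale parameters are resolved at fit time from the trait variance by
#' the usual R2-style partition: the prior mode of the total marker variance
#' accounts for \code{r2} of Var(y).
#'
#' @param family one of "BRR", "A", "B", "C", "BL".
#' @param dfBeta prior degrees of freedom for marker-variance terms
#'   (default 5).
#' @param scaleBeta prior scale S_beta; NA resolves from the data at fit
#'   time.
#' @param pi0 prior mean inclusion probability (B, C; default 0.5).
#' @param countsPi effective prior count of the beta prior on pi
#'   (default 10).
#' @param rScale,sScale gamma (shape, rate) hyperprior on S_beta (A, B);
#'   NA gives a weakly informative default anchored at the resolved scale.
#' @param rLambda,sLambda gamma (shape, rate) hyperprior on lambda^2 (BL).
#' @param r2 prior variance partition used to resolve scales (default 0.5).
#' @return list of class \code{priorSpec}.
#' @export
priorSpec <- function(family = c("BRR", "A", "B", "C", "BL"), dfBeta = 5,
                      scaleBeta = NA_real_, pi0 = 0.5, countsPi = 10,
                      rScale = NA_real_, sScale = NA_real_,
                      rLambda = 1.2, sLambda = NA_real_, r2 = 0.5) {
  family <- match.arg(family)
  if (dfBeta <= 0) stop("dfBeta must be positive")
  if (pi0 <= 0 || pi0 >= 1 || countsPi <= 0)
    stop("beta-prior parameters must be positive with pi0 in (0,1)")
  structure(list(family = family, dfBeta = dfBeta, scaleBeta = scaleBeta,
                 pi0 = pi0, countsPi = countsPi, rScale = rScale,
                 sScale = sScale, rLambda = rLambda, sLambda = sLambda,
                 r2 = r2), class = "priorSpec")
}

#' MCMC run control
#'
#' @param nIter total Gibbs iterations (default 5000).
#' @param burnIn discarded iterations (default 1000; must be < nIter).
#' @param thin keep every thin-th post-burn-in draw (default 5).
#' @param seed integer seed; chains are bit-reproducible.
#' @return list of class \code{mcmcConfig}.
#' @export
mcmcConfig <- function(nIter = 5000, burnIn = 1000, thin = 5, seed = 1L) {
  if (burnIn >= nIter) stop("burnIn must be smaller than nIter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmcConfig")
}

#' Fit a Bayesian-alphabet whole-genome regression by Gibbs sampling
#'
#' y = mu + X beta + e on centered (not standardized) genotype columns, so
#' marker effects stay in dosage units consistent with the variance-explained
#' formula. Fixed effects beyond the intercept are deliberately absent: the
#' trait is assumed pre-corrected. Conjugate updates throughout: per-locus
#' normal effects; scaled-inverse-chi-square variances (per locus for A/B
#' with a gamma-updated scale, common for BRR/C); spike-slab indicators with
#' a beta-updated inclusion probability (B, C); exponential-mixture latent
#' variances with a gamma-updated lambda^2 (BL).
#'
#' @param geno a \linkS4class{GenotypeData} or a numeric dosage matrix
#'   (training panel; missing dosages mean-imputed).
#' @param y trait vector (typically yc).
#' @param prior a \code{\link{priorSpec}}.
#' @param mcmc a \code{\link{mcmcConfig}}.
#' @param updateVarB,updateVarE,updatePi set FALSE to freeze the
#'   corresponding update (used for closed-form cross-checks).
#' @param varbInit,vareInit starting (or, when frozen, fixed) variance
#'   values; defaults follow the R2 partition.
#' @param keepTrace store the kept beta draws (small panels only).
#' @return object of class \code{bayesFit}: posterior means/SDs of beta,
#'   inclusion probabilities, mu, variance summaries, fitted values, centers
#'   used, the prior, and the kept-draw count.
#' @export
fitBayes <- function(geno, y, prior = priorSpec("BRR"),
                     mcmc = mcmcConfig(), updateVarB = TRUE,
                     updateVarE = TRUE, updatePi = TRUE,
                     varbInit = NULL, vareInit = NULL,
                     keepTrace = FALSE) {
  X <- if (is(geno, "GenotypeData")) dosages(geno) else as.matrix(geno)
  n <- nrow(X)
  if (length(y) != n) stop("y length must match individuals")
  ctr <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- ctr[(idx - 1) %/% n + 1]
  X <- sweep(X, 2L, ctr, "-")
  p <- ncol(X)

  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  msx <- sum(apply(X, 2, var))
  if (msx <= 0) msx <- 1
  r2 <- prior$r2
  piInit <- if (prior$family %in% c("B", "C")) prior$pi0 else 1
  varbMode <- r2 * vy / (msx * piInit)
  Sb <- prior$scaleBeta
  if (is.na(Sb)) Sb <- varbMode * (prior$dfBeta + 2) / prior$dfBeta
  rS <- prior$rScale
  sS <- prior$sScale
  if (prior$family %in% c("A", "B")) {
    if (is.na(rS)) rS <- 1.1
    if (is.na(sS)) sS <- (rS - 1) / Sb
  } else {
    rS <- 0
    sS <- 0
  }
  dfe <- 5
  Se <- (1 - r2) * vy * (dfe + 2) / dfe
  lambda2 <- 2 * (1 - r2) / r2 * msx / p
  if (!is.finite(lambda2) || lambda2 <= 0) lambda2 <- 1
  sL <- prior$sLambda
  if (is.na(sL)) sL <- (prior$rLambda - 1 + 1e-3) / lambda2

  fam <- match(prior$family, c("BRR", "A", "B", "C", "BL")) - 1L
  hp <- list(dfb = prior$dfBeta, Sb = Sb, dfe = dfe, Se = Se,
             pi0 = prior$pi0, p0 = prior$countsPi, rS = rS, sS = sS,
             rL = prior$rLambda, sL = sL, lambda2 = lambda2,
             vare = if (is.null(vareInit)) (1 - r2) * vy else vareInit,
             varb = if (is.null(varbInit)) varbMode else varbInit)

  set.seed(mcmc$seed)
  res <- bayes_gibbs_cpp(X, y, fam, hp, mcmc$nIter, mcmc$burnIn, mcmc$thin,
                         updateVarB, updateVarE, updatePi, keepTrace)
  structure(list(betaMean = res$beta_mean, betaSd = res$beta_sd,
                 inclProb = res$incl_prob, mu = res$mu,
                 sigma2e = res$vare, sigma2eSd = res$vare_sd,
                 sigma2b = res$varb, pi = res$pi, lambda2 = res$lambda2,
                 fitted = res$fitted, nKept = res$n_kept,
                 trace = res$trace, centers = ctr, prior = prior,
                 mcmc = mcmc),
            class = "bayesFit")
}

#' Predict from a Bayesian-alphabet fit
#'
#' prediction = mu + Z_new beta_hat, with Z_new centered at the training
#' column means (same panel, same centering as training).
#'
#' @param object a \code{bayesFit}.
#' @param newdata a \linkS4class{GenotypeData} or dosage matrix over the
#'   training SNP panel.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.bayesFit <- function(object, newdata, ...) {
  X <- if (is(newdata, "GenotypeData")) dosages(newdata) else
    as.matrix(newdata)
  if (ncol(X) != length(object$betaMean))
    stop("newdata SNP panel does not match the training panel")
  n <- nrow(X)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- object$centers[(idx - 1) %/% n + 1]
  Z <- sweep(X, 2L, object$centers, "-")
  as.numeric(object$mu + Z %*% object$betaMean)
}

#' @export
print.bayesFit <- function(x, ...) {
  cat("bayesFit (Bayes", x$prior$family, "):", length(x$betaMean),
      "markers,", x$nKept, "kept draws\n")
  cat("  posterior sigma2_e:", signif(x$sigma2e, 4))
  if (x$prior$family %in% c("B", "C"))
    cat("  pi:", signif(x$pi, 3))
  cat("\n")
  invisible(x)
}

#' Serialize a Bayesian fit's posterior summaries to JSON
#'
#' @param fit a \code{bayesFit}.
#' @param file output path.
#' @return invisibly, NULL.
#' @export
writeBayesFit <- function(fit, file) {
  out <- fit[c("betaMean", "betaSd", "inclProb", "mu", "sigma2e", "sigma2b",
               "pi", "lambda2", "nKept")]
  out$family <- fit$prior$family
  out$seed <- fit$mcmc$seed
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
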