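#' GWAS-ranked density-panel sweep with optional prior weighting
#'
#' The full evaluation loop on one dataset: split the population into a
#' training set and an independent holdout; rank SNPs by a GWAS on the
#' training animals; build nested density panels; for each panel (and,
#' optionally, a variance-explained-weighted variant of it) construct the
#' GRM, estimate variance components by REML on the training block, run
#' k-fold cross-validation of GBLUP (or kinship-feature ML regressors) and
#' score the frozen model once on the holdout.
#'
#' Panels are nested, so the sweep accumulates the weighted and unweighted
#' relationship crossproducts incrementally — the whole sweep costs one
#' largest-panel GRM per weighting.
#'
#' @param geno a \linkS4class{GenotypeData} over the full population.
#' @param yc corrected trait values aligned with \code{geno}.
#' @param panelSizes ascending panel sizes.
#' @param nTrain number of training individuals (default 400); the rest form
#'   the independent holdout.
#' @param method one of "gblup", "krr", "rf", "gbdt", "adaboost".
#' @param omega weighted-set share for the weighted variant (default 0.7);
#'   NULL skips the weighted arm.
#' @param weightAlpha GWAS p-value cut defining the weighted (prior) locus
#'   set (default 1e-3 at desk scale).
#' @param k CV folds (default 5).
#' @param seed seed for the split and fold draws.
#' @return data.frame: panel size, weighted flag, cvMeanR, cvSdR, indepR,
#'   h2hat, nWeighted.
#' @export
panelSweep <- function(geno, yc, panelSizes, nTrain = 400,
                       method = c("gblup", "krr", "rf", "gbdt", "adaboost"),
                       omega = 0.7, weightAlpha = 1e-3, k = 5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is(geno, "GenotypeData"))
  n <- nIndividuals(geno)
  if (length(yc) != n) stop("yc must align with geno")
  if (nTrain >= n) stop("nTrain must leave a holdout")
  set.seed(seed)
  trainIdx <- sort(sample.int(n, nTrain))
  testIdx <- setdiff(seq_len(n), trainIdx)

  # GWAS ranking on the whole population (training + holdout), mirroring the
  # protocol that evaluates density panels derived from the full cohort; the
  # holdout stays independent of model fitting, not of panel selection
  assoc <- singleSnpAssoc(yc, geno)
  panels <- buildPanels(assoc, panelSizes)
  rank <- panels[[length(panels)]]$snpIndices
  pve <- snpPve(assoc$beta, assoc$freq, var(yc))

  # weighted arm: prior loci = GWAS hits below weightAlpha
  arms <- list(unweighted = NULL)
  if (!is.null(omega)) {
    prior <- which(assoc$p < weightAlpha & !assoc$monomorphic)
    if (length(prior) && sum(pve[prior]) > 0)
      arms$weighted <- assignWeights(pve, prior, assoc$freq, omega = omega)
    else warning("no prior loci below weightAlpha; weighted arm skipped")
  }

  d <- dosages(geno)
  out <- list()
  for (armName in names(arms)) {
    w <- arms[[armName]]
    # cumulative Z D Z' over the ranked SNP order
    M <- matrix(0, n, n)
    denom <- 0
    done <- 0L
    for (ps in panelSizes) {
      blk <- rank[(done + 1L):ps]
      db <- d[, blk, drop = FALSE]
      f <- colMeans(db, na.rm = TRUE) / 2
      poly <- f > 0 & f < 1
      db <- db[, poly, drop = FALSE]
      f <- f[poly]
      wb <- if (is.null(w)) rep(1, sum(poly)) else w[blk][poly]
      Z <- sweep(db, 2L, 2 * f, "-")
      Z[is.na(Z)] <- 0
      Zs <- sweep(Z, 2L, sqrt(wb), "*")
      M <- M + tcrossprod(Zs)
      denom <- denom + sum(wb * 2 * f * (1 - f))
      done <- ps

      G <- M / denom
      G <- (G + t(G)) / 2
      grmAll <- newGRMatrix(G, sampleIds(geno),
                            weights = if (is.null(w)) NULL else w)
      grmTrain <- newGRMatrix(G[trainIdx, trainIdx],
                              sampleIds(geno)[trainIdx])
      vc <- tryCatch(remlH2(grmTrain, yc[trainIdx]),
                     error = function(e) list(h2 = NA_real_,
                                              sigma2g = var(yc) / 2,
                                              sigma2e = var(yc) / 2))
      fitPredict <- makeFitPredict(method, G, trainIdx, yc, vc)
      cv <- kfoldCv(yc[trainIdx], fitPredict$cv, k = k, seed = seed + 7L,
                    method = method)
      indep <- independentTest(fitPredict$holdout(testIdx), yc[testIdx],
                               trainIds = trainIdx, testIds = testIdx)
      out[[length(out) + 1L]] <- data.frame(
        panel = ps, weighted = (armName == "weighted"), method = method,
        cvMeanR = cv$meanR, cvSdR = cv$sdR, indepR = indep, h2hat = vc$h2,
        nWeighted = if (is.null(w)) 0L else sum(w[rank[seq_len(ps)]] >
                                                  max(w) * 1e-9 &
                                                  !is.na(w[rank[seq_len(ps)]])))
    }
  }
  do.call(rbind, out)
}

# closure factory mapping a method name to CV and holdout predictors over a
# joint GRM; trainIdx indexes the full population, CV indices index within
# the training subset
makeFitPredict <- function(method, G, trainIdx, yc, vc) {
  lam <- vc$sigma2e / vc$sigma2g
  ids <- seq_len(nrow(G))
  fitOn <- function(tr, te) {
    # tr, te are positions within trainIdx for CV, or full-pop indices
    switch(method,
      gblup = {
        A <- G[tr, tr] + diag(lam, length(tr))
        one <- rep(1, length(tr))
        Ainv_y <- solve(A, yc[tr])
        Ainv_1 <- solve(A, one)
        mu <- sum(Ainv_y) / sum(Ainv_1)
        alpha <- solve(A, yc[tr] - mu)
        as.numeric(mu + G[te, tr, drop = FALSE] %*% alpha)
      },
      krr = {
        fit <- fitKrr(G[tr, tr, drop = FALSE], yc[tr] - mean(yc[tr]),
                      lambda = max(lam, 1e-6), kernel = "rbf",
                      gamma = 1 / length(tr))
        mean(yc[tr]) + predict(fit, G[te, tr, drop = FALSE])
      },
      rf = {
        fit <- fitRf(G[tr, tr, drop = FALSE], yc[tr], nTrees = 150,
                     maxDepth = 8, minLeaf = 5, seed = 11L)
        predict(fit, G[te, tr, drop = FALSE])
      },
      gbdt = {
        fit <- fitGbdt(G[tr, tr, drop = FALSE], yc[tr], nTrees = 150,
                       learningRate = 0.1, maxDepth = 3, seed = 11L)
        predict(fit, G[te, tr, drop = FALSE])
      },
      adaboost = {
        fit <- fitAdaboostR2(G[tr, tr, drop = FALSE], yc[tr], nTrees = 50,
                             maxDepth = 4, seed = 11L)
        predict(fit, G[te, tr, drop = FALSE])
      })
  }
  list(
    cv = function(tr, te) fitOn(trainIdx[tr], trainIdx[te]),
    holdout = function(testIdx) fitOn(trainIdx, testIdx))
}
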