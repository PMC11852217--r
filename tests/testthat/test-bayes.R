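test_that("GBLUP interpolates in the noise-free limit and is equivariant", {
  set.seed(40)
  g <- makeNullGeno(40, 200, seed = 40)
  G <- vanRadenGrm(g)
  yc <- as.numeric(scale(rnorm(40) + rowSums(dosages(g)[, 1:5])))

  fit <- fitGblup(G, yc, sigma2g = 1, sigma2e = 1e-10)
  expect_equal(fit$fitted, yc, tolerance = 1e-4)

  fit2 <- fitGblup(G, yc, sigma2g = 1, sigma2e = 0.5)
  perm <- sample(40)
  Gp <- pigGP:::newGRMatrix(grmValues(G)[perm, perm], sampleIds(G)[perm])
  fitP <- fitGblup(Gp, yc[perm], sigma2g = 1, sigma2e = 0.5)
  expect_equal(fitP$gebv, fit2$gebv[perm], tolerance = 1e-8)
  # centered-marker GRM rows sum to zero, so GEBVs sum to zero
  expect_lt(abs(sum(fit2$gebv)), 1e-8)
})

test_that("GBLUP equals linear-kernel KRR at lambda = sigma2e/sigma2g", {
  set.seed(41)
  g <- makeNullGeno(50, 300, seed = 41)
  G <- vanRadenGrm(g)
  yc <- as.numeric(scale(rnorm(50) + rowSums(dosages(g)[, 1:8])))
  yc <- yc - mean(yc)
  s2g <- 0.6; s2e <- 0.4
  fg <- fitGblup(G, yc, sigma2g = s2g, sigma2e = s2e, estimateMu = FALSE)
  fk <- fitKrr(grmValues(G), yc, lambda = s2e / s2g)
  expect_lt(max(abs(fg$fitted - predict(fk, grmValues(G)))), 1e-8)
  # prediction path: G[test,train] weights give the same as the KRR rows
  expect_equal(predict(fg, grmValues(G)[1:10, , drop = FALSE]),
               predict(fk, grmValues(G)[1:10, , drop = FALSE]),
               tolerance = 1e-8)
})

test_that("null data shrinks every posterior marker effect to zero", {
  set.seed(42)
  g <- makeNullGeno(60, 80, seed = 42)
  for (fam in c("BRR", "A", "B", "C", "BL")) {
    fit <- fitBayes(g, rep(0, 60), priorSpec(fam),
                    mcmcConfig(800, 300, 2, seed = 43))
    expect_true(all(abs(fit$betaMean) <=
                      3 * pmax(fit$betaSd, 1e-8) + 1e-6),
                info = fam)
  }
})

test_that("seeded chains are bit-reproducible", {
  g <- makeNullGeno(40, 50, seed = 44)
  y <- rnorm(40)
  f1 <- fitBayes(g, y, priorSpec("B"), mcmcConfig(400, 100, 2, seed = 7))
  f2 <- fitBayes(g, y, priorSpec("B"), mcmcConfig(400, 100, 2, seed = 7))
  expect_identical(f1$betaMean, f2$betaMean)
  expect_identical(f1$sigma2e, f2$sigma2e)
})

test_that("fixed-variance BRR agrees with the ridge closed form", {
  set.seed(45)
  n <- 30; p <- 50
  g <- makeNullGeno(n, p, seed = 45)
  X <- scale(dosages(g), scale = FALSE)
  b <- rnorm(p, 0, 0.1)
  y <- as.numeric(X %*% b + rnorm(n, 0, 0.5))
  varb <- 0.02; vare <- 0.25
  fit <- fitBayes(g, y, priorSpec("BRR"), mcmcConfig(6000, 1000, 1, seed = 9),
                  updateVarB = FALSE, updateVarE = FALSE,
                  varbInit = varb, vareInit = vare, keepTrace = TRUE)
  ridge <- solve(crossprod(X) + diag(vare / varb, p), crossprod(X, y))
  # Monte-Carlo SE per coordinate from 25 batch means
  tr <- fit$trace
  nb <- 25
  bsize <- floor(nrow(tr) / nb)
  bm <- sapply(seq_len(nb), function(b)
    colMeans(tr[((b - 1) * bsize + 1):(b * bsize), , drop = FALSE]))
  mcse <- apply(bm, 1, sd) / sqrt(nb)
  diff <- abs(fit$betaMean - as.numeric(ridge))
  expect_true(all(diff < 3 * mcse + 2e-3))
})

test_that("Bayes C with inclusion forced on matches BRR", {
  set.seed(46)
  n <- 50; p <- 40
  g <- makeNullGeno(n, p, seed = 46)
  y <- as.numeric(scale(dosages(g)[, 1] + rnorm(n)))
  mc <- mcmcConfig(4000, 1000, 1, seed = 11)
  fC <- fitBayes(g, y, priorSpec("C", pi0 = 1 - 1e-9), mc, updatePi = FALSE)
  fR <- fitBayes(g, y, priorSpec("BRR"), mc)
  expect_true(all(fC$inclProb > 0.999))
  expect_gt(cor(fC$betaMean, fR$betaMean), 0.98)
  expect_lt(max(abs(fC$fitted - fR$fitted)), 0.1 * sd(y))
  expect_lt(abs(fC$sigma2e - fR$sigma2e), 3 * (fC$sigma2eSd + fR$sigma2eSd))
})

test_that("Bayes B concentrates inclusion on planted QTL", {
  cfg <- simConfig(nIndividuals = 400, nSnps = 500, nChromosomes = 2,
                   withinBlockCorr = 0.3, nQtl = 5, h2 = 0.5,
                   fixedEffectLevels = integer(0), seed = 47)
  g <- simulateGenotypes(cfg)
  sp <- simulatePhenotypes(g, cfg)
  yc <- as.numeric(scale(sp$pheno$phenotype))
  fit <- fitBayes(g, yc, priorSpec("B", pi0 = 0.05),
                  mcmcConfig(1500, 500, 2, seed = 48))
  top20 <- order(fit$inclProb, decreasing = TRUE)[1:20]
  expect_gte(sum(sp$truth$qtlIndices %in% top20), 4)
})

test_that("posterior variance bookkeeping approximately conserves Var(y)", {
  cfg <- simConfig(nIndividuals = 300, nSnps = 200, nChromosomes = 2,
                   nQtl = 20, h2 = 0.5, fixedEffectLevels = integer(0),
                   seed = 49)
  g <- simulateGenotypes(cfg)
  yc <- as.numeric(scale(simulatePhenotypes(g, cfg)$pheno$phenotype))
  for (fam in c("BRR", "A", "BL")) {
    fit <- fitBayes(g, yc, priorSpec(fam), mcmcConfig(1200, 400, 2, seed = 50))
    total <- fit$sigma2e + var(fit$fitted)
    expect_lt(abs(total - var(yc)), 0.35 * var(yc))
  }
})

test_that("Bayes predictions honor centering, location shifts and panels", {
  set.seed(51)
  g <- makeNullGeno(50, 30, seed = 51)
  y <- rnorm(50)
  fit <- fitBayes(g, y, priorSpec("BRR"), mcmcConfig(600, 200, 2, seed = 12))
  expect_equal(predict(fit, g), fit$fitted, tolerance = 1e-10)

  fit2 <- fitBayes(g, y + 10, priorSpec("BRR"),
                   mcmcConfig(600, 200, 2, seed = 12))
  expect_equal(predict(fit2, g), predict(fit, g) + 10, tolerance = 1e-8)

  expect_error(predict(fit, dosages(g)[, 1:10]), "panel")

  # one-line arithmetic on a single-SNP toy
  d1 <- cbind(c(0, 1, 2, 1, 0, 2))
  gf <- makeGeno(d1)
  f1 <- fitBayes(gf, c(0, 1, 2, 1, 0, 2), priorSpec("BRR"),
                 mcmcConfig(2000, 500, 1, seed = 13))
  znew <- cbind(c(2, 0))
  expect_equal(predict(f1, znew),
               f1$mu + (znew - mean(d1)) * f1$betaMean,
               tolerance = 1e-10, ignore_attr = TRUE)
})
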