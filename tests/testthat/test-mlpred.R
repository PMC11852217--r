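test_that("GRM-row features are plain index arithmetic", {
  set.seed(60)
  g <- makeNullGeno(5, 40, seed = 60)
  G <- suppressWarnings(vanRadenGrm(g))  # tiny fixture: monomorphic columns
  ids <- sampleIds(G)
  FV <- makeGrmFeatures(G, trainIds = ids[1:3], queryIds = ids[4:5])
  expect_equal(dim(FV), c(2L, 3L))
  for (i in 1:2) for (j in 1:3)
    expect_equal(FV[i, j], grmValues(G)[i + 3, j])

  FVt <- makeGrmFeatures(G, ids[1:3], ids[1:3])
  expect_equal(unname(FVt), unname(grmValues(G)[1:3, 1:3]))

  permCols <- c(3, 1, 2)
  FVp <- makeGrmFeatures(G, ids[permCols], ids[4:5])
  expect_equal(unname(FVp), unname(FV[, permCols]))
  expect_error(makeGrmFeatures(G, ids[1:3], "nobody"), "unknown id")
})

test_that("KRR reproduces closed forms, limits and a direct-solve oracle", {
  # K = I, lambda = 1, k' = e_j  =>  prediction y_j / 2
  y <- c(4, -2, 6, 1)
  fit <- fitKrr(diag(4), y, lambda = 1)
  expect_equal(predict(fit, diag(4)), y / 2, tolerance = 1e-12)

  set.seed(61)
  X <- matrix(rnorm(20 * 40), 20, 40)
  K <- tcrossprod(X) / 40       # full rank: lambda -> 0 interpolates
  y2 <- rnorm(20)
  fitI <- fitKrr(K, y2, lambda = 1e-10)
  expect_equal(predict(fitI, K), y2, tolerance = 1e-6)

  lam <- 0.37
  fit2 <- fitKrr(K, y2, lambda = lam)
  direct <- solve(K + lam * diag(20)) %*% y2   # independent direct solve
  kRows <- K[1:7, , drop = FALSE]
  expect_lt(max(abs(predict(fit2, kRows) - kRows %*% direct)), 1e-10)

  expect_error(fitKrr(K, y2, lambda = 0), "positive")
  Kbad <- K; Kbad[1, 2] <- Kbad[1, 2] + 1
  expect_error(fitKrr(Kbad, y2, lambda = 1), "symmetric")
})

test_that("RBF-kernel KRR predicts from feature rows", {
  set.seed(62)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- sin(X[, 1]) + rnorm(40, 0, 0.1)
  fit <- fitKrr(X, y, lambda = 0.1, kernel = "rbf", gamma = 0.3)
  expect_gt(cor(predict(fit, X), y), 0.8)
})

test_that("CART finds a planted step and behaves on degenerate targets", {
  x <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), ncol = 1)
  y <- c(0, 0, 0, 0, 5, 5, 5, 5)
  tr <- fitTree(x, y, maxDepth = 1, minLeaf = 1)
  expect_equal(tr$feature[1], 0L)          # split on the only feature
  expect_equal(tr$threshold[1], 7)         # midpoint of the step boundary
  expect_equal(predict(tr, x), y)

  trC <- fitTree(x, rep(3, 8), maxDepth = 4, minLeaf = 1)
  expect_equal(length(trC$value), 1L)
  expect_equal(predict(trC, x), rep(3, 8))
})

test_that("deeper trees never increase training MSE", {
  set.seed(63)
  X <- matrix(rnorm(150 * 5), 150, 5)
  y <- X[, 1] * 2 + X[, 2]^2 + rnorm(150, 0, 0.2)
  mse <- vapply(1:6, function(d) {
    mean((predict(fitTree(X, y, maxDepth = d, minLeaf = 2), X) - y)^2)
  }, numeric(1))
  expect_true(all(diff(mse) <= 1e-12))
})

test_that("weighted tree fits respect sample weights", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c(0, 0, 10, 10)
  w <- c(1, 1, 0, 0)
  tr <- fitTree(x, y, maxDepth = 2, minLeaf = 1, weights = w)
  expect_equal(predict(tr, x)[1:2], c(0, 0))
})

test_that("a one-tree unbagged forest reduces to a single tree", {
  set.seed(64)
  X <- matrix(rnorm(80 * 4), 80, 4)
  y <- X[, 1] + rnorm(80, 0, 0.3)
  rf1 <- fitRf(X, y, nTrees = 1, bag = FALSE, mtryFrac = 1, maxDepth = 4,
               seed = 1)
  tr <- fitTree(X, y, maxDepth = 4)
  expect_identical(predict(rf1, X), predict(tr, X))
})

test_that("forest prediction is the mean of member trees and bagging helps", {
  set.seed(65)
  n <- 200
  X <- matrix(runif(n * 5), n, 5)
  y <- 10 * sin(pi * X[, 1] * X[, 2]) + 20 * (X[, 3] - 0.5)^2 +
    10 * X[, 4] + 5 * X[, 5] + rnorm(n)
  Xt <- matrix(runif(n * 5), n, 5)
  yt <- 10 * sin(pi * Xt[, 1] * Xt[, 2]) + 20 * (Xt[, 3] - 0.5)^2 +
    10 * Xt[, 4] + 5 * Xt[, 5] + rnorm(n)

  rf <- fitRf(X, y, nTrees = 100, maxDepth = 8, minLeaf = 3, seed = 2)
  member <- predict(rf, Xt, individual = TRUE)
  expect_equal(predict(rf, Xt), rowMeans(member), tolerance = 1e-12)

  mseTree <- mean((predict(fitTree(X, y, maxDepth = 8, minLeaf = 3), Xt)
                   - yt)^2)
  mseRf <- mean((predict(rf, Xt) - yt)^2)
  expect_lt(mseRf, mseTree)
})

test_that("forest fits are seed-reproducible", {
  set.seed(66)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rnorm(60)
  r1 <- predict(fitRf(X, y, nTrees = 20, seed = 5), X)
  r2 <- predict(fitRf(X, y, nTrees = 20, seed = 5), X)
  expect_identical(r1, r2)
})

test_that("GBDT base model, exact stump stage and monotone training MSE", {
  set.seed(67)
  X <- matrix(rnorm(100 * 3), 100, 3)
  y <- rnorm(100)
  g0 <- fitGbdt(X, y, nTrees = 0)
  expect_equal(predict(g0, X), rep(mean(y), 100))

  # a single depth-1 stage at learning rate 1 nails a 2-level step exactly
  xs <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  ys <- c(1, 1, 1, 4, 4, 4)
  g1 <- fitGbdt(xs, ys, nTrees = 1, learningRate = 1, maxDepth = 1,
                minLeaf = 1)
  expect_equal(predict(g1, xs), ys, tolerance = 1e-12)

  y2 <- X[, 1] + 0.5 * X[, 2] + rnorm(100, 0, 0.2)
  mse <- vapply(c(1, 5, 20, 60), function(M) {
    mean((predict(fitGbdt(X, y2, nTrees = M, learningRate = 0.3,
                          maxDepth = 2, minLeaf = 2), X) - y2)^2)
  }, numeric(1))
  expect_true(all(diff(mse) <= 1e-10))
})

test_that("GOSS with keep-all is bit-identical to plain GBDT", {
  set.seed(68)
  X <- matrix(rnorm(90 * 4), 90, 4)
  y <- X[, 1] - X[, 3] + rnorm(90, 0, 0.3)
  gA <- fitGbdt(X, y, nTrees = 30, seed = 3)
  gB <- fitGbdt(X, y, nTrees = 30, gossA = 1, gossB = 0.2, seed = 3)
  expect_identical(predict(gA, X), predict(gB, X))

  gC <- fitGbdt(X, y, nTrees = 30, gossA = 0.3, gossB = 0.3, seed = 3)
  expect_gt(cor(predict(gC, X), y), 0.8)  # sampling variant still learns
})

test_that("AdaBoost.R2 weighted-median combination follows the inequality", {
  # weights {1.0, 0.1}, predictions {2, 7}: first weight holds the half
  expect_equal(pigGP:::weightedMedian(c(2, 7), c(1.0, 0.1)), 2)
  expect_equal(pigGP:::weightedMedian(c(7, 2), c(0.1, 1.0)), 2)
  # equal weights: infimum semantics take the smaller middle value
  expect_equal(pigGP:::weightedMedian(c(1, 3), c(1, 1)), 1)

  set.seed(69)
  X <- matrix(rnorm(80 * 3), 80, 3)
  y <- X[, 1] + rnorm(80, 0.1)
  ab1 <- fitAdaboostR2(X, y, nTrees = 1, maxDepth = 3)
  tr <- fitTree(X, y, maxDepth = 3, weights = rep(1 / 80, 80))
  expect_identical(predict(ab1, X), predict(tr, X))

  ab <- fitAdaboostR2(X, y, nTrees = 25, maxDepth = 3, seed = 4)
  expect_gt(cor(predict(ab, X), y), 0.75)
  expect_true(all(ab$epsilons < 1))
})

test_that("identical learners give their common output as the median", {
  xs <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  ys <- c(1, 1, 1, 4, 4, 4)  # separable: every round fits exactly
  ab <- fitAdaboostR2(xs, ys, nTrees = 5, maxDepth = 1, minLeaf = 1)
  expect_equal(predict(ab, xs), ys, tolerance = 1e-12)
})

test_that("linear-kernel KRR on the GRM reproduces GBLUP ranking", {
  set.seed(70)
  g <- makeNullGeno(60, 250, seed = 70)
  G <- vanRadenGrm(g)
  yc <- as.numeric(scale(rnorm(60) + rowSums(dosages(g)[, 1:6])))
  s2g <- 0.5; s2e <- 0.5
  fg <- fitGblup(G, yc, sigma2g = s2g, sigma2e = s2e, estimateMu = FALSE)
  fk <- fitKrr(grmValues(G), yc, lambda = s2e / s2g)
  expect_equal(cor(fg$gebv, predict(fk, grmValues(G)),
                   method = "spearman"), 1)
})

test_that("all five regressors beat chance and respect the noise ceiling", {
  cfg <- simConfig(nIndividuals = 300, nSnps = 600, nChromosomes = 3,
                   nQtl = 30, h2 = 0.5, fixedEffectLevels = integer(0),
                   seed = 71)
  g <- simulateGenotypes(cfg)
  yc <- as.numeric(scale(simulatePhenotypes(g, cfg)$pheno$phenotype))
  G <- grmValues(vanRadenGrm(g))
  tr <- 1:200
  te <- 201:300
  Xtr <- G[tr, tr]
  Xte <- G[te, tr]
  preds <- list(
    krr = predict(fitKrr(Xtr, yc[tr], lambda = 1, kernel = "rbf",
                         gamma = 1 / 200), Xte),
    tree = predict(fitTree(Xtr, yc[tr], maxDepth = 5), Xte),
    rf = predict(fitRf(Xtr, yc[tr], nTrees = 100, seed = 1), Xte),
    gbdt = predict(fitGbdt(Xtr, yc[tr], nTrees = 100, seed = 1), Xte),
    ada = predict(fitAdaboostR2(Xtr, yc[tr], nTrees = 30, seed = 1), Xte))
  for (m in names(preds)) {
    r <- accuracy(preds[[m]], yc[te])
    expect_gt(r, 0)
    expect_lt(r, sqrt(0.5) + 0.15)   # noise ceiling sqrt(h2) plus slack
  }
})
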