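test_that("VanRaden GRM matches a pencil-and-paper computation", {
  d <- matrix(c(0, 1, 2, 1,
                2, 0, 1, 1,
                1, 1, 0, 2), 3, 4, byrow = TRUE)
  g <- makeGeno(d)
  G <- grmValues(vanRadenGrm(g))
  # by hand: f per SNP, Z = d - 2f, G = ZZ' / (2 sum f(1-f))
  f <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * f, "-")
  Ghand <- Z %*% t(Z) / (2 * sum(f * (1 - f)))
  expect_equal(G, Ghand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical individuals share identical GRM rows", {
  set.seed(30)
  d <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50)
  d[2, ] <- d[1, ]
  G <- grmValues(vanRadenGrm(makeGeno(d)))
  expect_equal(G[1, ], G[2, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(G[1, 2], G[1, 1], tolerance = 1e-12)
})

test_that("unrelated simulated population has mean diagonal near one", {
  cfg <- simConfig(nIndividuals = 400, nSnps = 2000, nChromosomes = 4,
                   withinBlockCorr = 0, seed = 31)
  G <- vanRadenGrm(simulateGenotypes(cfg))
  expect_lt(abs(mean(diag(grmValues(G))) - 1), 0.05)
  ev <- eigen(grmValues(G), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("monomorphic SNPs are excluded with a warning", {
  d <- cbind(rbinom(30, 2, 0.4), rep(0, 30), rbinom(30, 2, 0.3))
  expect_warning(G <- vanRadenGrm(makeGeno(d)), "monomorphic")
  G2 <- vanRadenGrm(makeGeno(d[, c(1, 3)]))
  expect_equal(grmValues(G), grmValues(G2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("prior weights follow the omega-share rescaling", {
  # two SNPs at f=0.5 (h=0.5 each), pve (0.3, 0.1), SNP 1 weighted, w=0.7:
  # T = 1; c = 0.7*T/(0.3*0.5) = 14/3; w1 = 0.3*c = 1.4; w2 = 0.3*T/0.5 = 0.6
  w <- assignWeights(pve = c(0.3, 0.1), weightedSet = 1,
                     freq = c(0.5, 0.5), omega = 0.7)
  expect_equal(w, c(1.4, 0.6), tolerance = 1e-12)
  h <- 2 * 0.5 * 0.5
  expect_equal(w[1] * h / sum(w * h), 0.7, tolerance = 1e-12)
  expect_error(assignWeights(c(0.1, 0.2), integer(0), c(0.5, 0.5)), "empty")
  expect_error(assignWeights(c(0, 0), 1:2, c(0.5, 0.5)), "zero total")
})

test_that("weighting the whole panel uniformly reduces to the plain GRM", {
  set.seed(32)
  g <- makeNullGeno(40, 60, seed = 32)
  f <- colMeans(dosages(g)) / 2
  w <- assignWeights(pve = rep(0.01, 60), weightedSet = 1:60, freq = f,
                     omega = 0.5)
  expect_equal(grmValues(weightedGrm(g, w)), grmValues(vanRadenGrm(g)),
               tolerance = 1e-12)
})

test_that("weighted GRM reduces, excludes and rescales as algebra demands", {
  set.seed(33)
  g <- makeNullGeno(30, 40, seed = 33)
  Gu <- grmValues(vanRadenGrm(g))
  expect_equal(grmValues(weightedGrm(g, rep(1, 40))), Gu, tolerance = 1e-12)

  w <- c(0, rep(1, 39))
  expect_equal(grmValues(weightedGrm(g, w)),
               grmValues(vanRadenGrm(g[, 2:40])), tolerance = 1e-12)

  w2 <- runif(40, 0.1, 2)
  expect_equal(grmValues(weightedGrm(g, w2)),
               grmValues(weightedGrm(g, 2 * w2)), tolerance = 1e-12)
  expect_error(weightedGrm(g, c(-1, rep(1, 39))), "non-negative")
})

test_that("GRM is equivariant under individual reordering", {
  set.seed(34)
  g <- makeNullGeno(25, 50, seed = 34)
  G <- grmValues(vanRadenGrm(g))
  perm <- sample(25)
  Gp <- grmValues(vanRadenGrm(g[perm, ]))
  expect_equal(Gp, G[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("REML recovers boundary and null heritability regimes", {
  cfg <- simConfig(nIndividuals = 300, nSnps = 800, nChromosomes = 2,
                   nQtl = 40, h2 = 1, fixedEffectLevels = integer(0),
                   seed = 35)
  g <- simulateGenotypes(cfg)
  sp <- simulatePhenotypes(g, cfg)
  G <- vanRadenGrm(g)
  fitHi <- remlH2(G, sp$pheno$phenotype)
  expect_gt(fitHi$h2, 0.9)

  # permuted phenotype: genetic signal destroyed
  set.seed(36)
  h2null <- vapply(1:8, function(i) {
    remlH2(G, sample(sp$pheno$phenotype))$h2
  }, numeric(1))
  expect_lt(mean(h2null), 0.08)
  expect_lt(median(h2null), 0.05)
})

test_that("REML is invariant to affine trait rescaling", {
  cfg <- simConfig(nIndividuals = 250, nSnps = 600, nChromosomes = 2,
                   nQtl = 30, h2 = 0.4, seed = 37)
  g <- simulateGenotypes(cfg)
  y <- simulatePhenotypes(g, cfg)$pheno$phenotype
  G <- vanRadenGrm(g)
  f1 <- remlH2(G, y)
  f2 <- remlH2(G, 5 * y - 3)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_true(f1$converged)
  expect_gt(f1$se, 0)
})

test_that("GCTA-style triplet export round-trips the matrix", {
  g <- makeNullGeno(8, 30, seed = 38)
  G <- suppressWarnings(vanRadenGrm(g))  # tiny fixture: monomorphic columns
  pre <- file.path(tempdir(), "grmtest")
  writeGctaGrm(G, pre, nSnpsUsed = 30L)
  trip <- read.table(paste0(pre, ".grm.txt"))
  ids <- read.table(paste0(pre, ".grm.id"))
  expect_equal(nrow(trip), 8 * 9 / 2)
  expect_equal(as.character(ids$V2), sampleIds(G))
  M <- matrix(0, 8, 8)
  M[cbind(trip$V1, trip$V2)] <- trip$V4
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  expect_equal(M, unname(grmValues(G)), tolerance = 1e-12)
})
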