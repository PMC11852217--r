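test_that("per-SNP stats match hand-derived cases", {
  # all-het SNP: f=0.5, expected counts (25, 50, 25), chi2 = 25+50+25 = 100
  g <- makeGeno(cbind(rep(1, 100)))
  st <- snpSummary(g)
  expect_equal(st$maf, 0.5)
  expect_lt(st$hweP, 1e-6)
  expect_equal(st$hweP, pchisq(100, 1, lower.tail = FALSE))

  # exact HWE proportions: chi-square 0, p = 1
  g2 <- makeGeno(cbind(rep(c(0, 1, 2), times = c(25, 50, 25))))
  expect_equal(snpSummary(g2)$hweP, 1)

  # 10% missing entries -> call rate 0.9
  v <- rep(c(0, 1, 2, NA), times = c(40, 30, 20, 10))
  expect_equal(snpSummary(makeGeno(cbind(v)))$callRate, 0.9)

  # all-missing SNP flagged undefined
  st3 <- snpSummary(makeGeno(cbind(rep(NA_real_, 10), rep(1, 10))))
  expect_equal(st3$callRate[1], 0)
  expect_true(is.na(st3$maf[1]) && is.na(st3$hweP[1]))
  expect_true(st3$monomorphic[1])
})

test_that("QC ledger arithmetic is enforced at construction", {
  led <- qcLedger(57466, c(no_position_or_sex_chrom = 9435, qc = 16275))
  expect_equal(led$finalSnps, 31756)
  expect_equal(led$initialSnps - sum(led$removedByStage), led$finalSnps)
  expect_error(qcLedger(10, c(a = 20)), "exceed")
  expect_error(qcLedger(10, c(a = -1)), "non-negative")
})

test_that("staged QC removes exactly the planted failures and is idempotent", {
  set.seed(10)
  n <- 200
  good <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  lowMaf <- c(rep(0, n - 1), 1)            # planted MAF = 1/(2n) = 0.0025
  lowCall <- rbinom(n, 2, 0.3)
  lowCall[1:20] <- NA                      # call rate 0.9 < 0.95
  allHet <- rep(1, n)                      # extreme HWE failure
  d <- cbind(good[, 1:2], lowMaf, good[, 3:4], lowCall, allHet, good[, 5:6])
  g <- genotypeData(d, snpMeta = data.frame(
    id = paste0("s", 1:9),
    chrom = c("1", "1", "1", "1", "X", "1", "1", "1", "2"),
    pos = c(1:4, 5, 6:7, 8, NA), a1 = "A", a2 = "G"))

  res <- applyQc(g, qcThresholds())
  led <- res$ledger
  expect_equal(unname(led$removedByStage["no_position_or_sex_chrom"]), 2L)
  expect_equal(unname(led$removedByStage["call_rate"]), 1L)
  expect_equal(unname(led$removedByStage["maf"]), 1L)
  expect_equal(unname(led$removedByStage["hwe"]), 1L)
  expect_equal(led$finalSnps, 4L)
  expect_false("s3" %in% colnames(dosages(res$geno)))  # the planted MAF SNP

  res2 <- applyQc(res$geno, qcThresholds())
  expect_identical(dosages(res2$geno), dosages(res$geno))
  expect_equal(sum(res2$ledger$removedByStage), 0L)
})

test_that("near-zero thresholds only remove the positional stage", {
  set.seed(11)
  d <- matrix(rbinom(100 * 5, 2, 0.4), 100, 5)
  d[1:50, 3] <- NA
  g <- genotypeData(d, snpMeta = data.frame(
    id = paste0("s", 1:5), chrom = c("1", "X", "1", "1", "1"),
    pos = 1:5, a1 = "A", a2 = "G"))
  res <- applyQc(g, qcThresholds(minCallRate = 1e-9, minMaf = 0,
                                 hweAlpha = 1e-300))
  expect_equal(sum(res$ledger$removedByStage), 1L)
  expect_equal(unname(res$ledger$removedByStage["no_position_or_sex_chrom"]),
               1L)
})

test_that("imputation concordance reproduces direct ratios and bins", {
  set.seed(12)
  d <- matrix(rbinom(30 * 20, 2, 0.4), 30, 20)
  truth <- makeGeno(d)
  expect_equal(imputationConcordance(truth, truth)$meanAccuracy, 1)

  d2 <- d
  d2[1, 5] <- (d2[1, 5] + 1) %% 3   # one wrong individual at one SNP
  imp <- makeGeno(d2)
  rep_ <- imputationConcordance(imp, truth)
  expect_equal(unname(rep_$perSnpAccuracy["s5"]), 29 / 30)
  expect_equal(rep_$meanAccuracy, mean(rep_$perSnpAccuracy))
  expect_equal(rep_$bins$threshold, c(0.3, 0.6, 0.9))
  expect_setequal(rep_$perfectSnps, paste0("s", setdiff(1:20, 5)))

  expect_error(imputationConcordance(truth[, 1:5], truth), "SNP set")
})

test_that("concordance is invariant to individual and SNP order", {
  set.seed(13)
  d <- matrix(rbinom(20 * 10, 2, 0.3), 20, 10)
  truth <- makeGeno(d)
  d2 <- d
  d2[3, 2] <- (d2[3, 2] + 1) %% 3
  imp <- makeGeno(d2)
  r1 <- imputationConcordance(imp, truth)
  permI <- sample(20)
  permJ <- sample(10)
  # same dosages with relabeled rows and re-ordered SNP columns (ids travel
  # with their columns; positions are fresh so the container stays valid)
  imp2 <- genotypeData(
    d2[permI, permJ],
    snpMeta = data.frame(id = paste0("s", permJ), chrom = "1", pos = 1:10,
                         a1 = "A", a2 = "G"),
    sampleIds = paste0("ind_", permI))
  r2 <- imputationConcordance(imp2, truth)
  expect_equal(r1$meanAccuracy, r2$meanAccuracy)
  expect_equal(r1$perSnpAccuracy[sort(names(r1$perSnpAccuracy))],
               r2$perSnpAccuracy[sort(names(r2$perSnpAccuracy))])
})
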