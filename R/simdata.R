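#' Simulate block-LD genotypes
#'
#' Genotypes are sampled as pairs of haplotypes from a block-wise
#' Gaussian-copula threshold model: within each LD block a latent AR(1)
#' Gaussian process with correlation \code{withinBlockCorr} is thresholded at
#' the per-SNP allele-frequency quantile, so each SNP is marginally in
#' Hardy-Weinberg proportions while adjacent SNPs within a block share
#' positive dosage correlation. Blocks (and chromosomes) are independent.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{GenotypeData}; dosages count copies of the minor
#'   allele.
#' @examples
#' geno <- simulateGenotypes(simConfig(nIndividuals = 50, nSnps = 200))
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nIndividuals
  m <- cfg@nSnps
  rho <- cfg@withinBlockCorr

  # spread SNPs over chromosomes as evenly as possible
  perChrom <- rep(m %/% cfg@nChromosomes, cfg@nChromosomes)
  extra <- m %% cfg@nChromosomes
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  chrom <- rep(seq_len(cfg@nChromosomes), perChrom)

  maf <- runif(m, cfg@mafRange[1], cfg@mafRange[2])
  pos <- unlist(lapply(perChrom, function(k) {
    cumsum(1000L + floor(runif(k) * 50000))
  }), use.names = FALSE)

  # latent haplotypes: 2n rows, AR(1) within blocks, blocks independent
  dos <- matrix(0, n, m)
  start <- 1L
  for (cc in seq_len(cfg@nChromosomes)) {
    k <- perChrom[cc]
    if (k == 0L) next
    cols <- start:(start + k - 1L)
    nblocks <- ceiling(k / cfg@ldBlockSize)
    for (b in seq_len(nblocks)) {
      j0 <- (b - 1L) * cfg@ldBlockSize + 1L
      j1 <- min(b * cfg@ldBlockSize, k)
      B <- j1 - j0 + 1L
      Z <- matrix(rnorm(2L * n * B), 2L * n, B)
      if (rho > 0 && B > 1L) {
        for (t in 2:B) Z[, t] <- rho * Z[, t - 1L] + sqrt(1 - rho^2) * Z[, t]
      }
      thr <- qnorm(maf[cols[j0:j1]])
      alle <- sweep(Z, 2L, thr, "<")
      dos[, cols[j0:j1]] <- alle[seq_len(n), , drop = FALSE] +
        alle[n + seq_len(n), , drop = FALSE]
    }
    start <- start + k
  }

  if (cfg@missingRate > 0) {
    nmiss <- rbinom(1L, n * m, cfg@missingRate)
    if (nmiss > 0) dos[sample.int(n * m, nmiss)] <- NA_real_
  }

  alleles <- matrix(sample(c("A", "C", "G", "T"), 2L * m, replace = TRUE),
                    m, 2L)
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- ifelse(alleles[same, 1] == "A", "G", "A")
  meta <- data.frame(id = sprintf("snp_%d_%d", chrom, pos), chrom = as.character(chrom),
                     pos = pos, a1 = alleles[, 1], a2 = alleles[, 2],
                     stringsAsFactors = FALSE)
  genotypeData(dos, snpMeta = meta,
               sampleIds = sprintf("ind_%04d", seq_len(n)))
}

#' Simulate phenotypes with an additive sparse-QTL architecture
#'
#' Phenotype = categorical fixed-effect contributions + additive breeding
#' value + Gaussian noise. QTL effects are drawn N(0, 1) and rescaled so the
#' sample variance of the breeding values equals \code{h2} (genetic plus
#' residual variance is 1 in expectation), hence
#' Var(g)/Var(g + e) approximates \code{h2}. Fixed-effect levels are assigned
#' uniformly and level effects drawn N(0, fixedEffectSd^2).
#'
#' @param geno a \linkS4class{GenotypeData}; QTL columns must be complete.
#' @param cfg the \linkS4class{SimConfig} used (its seed governs this draw
#'   too, offset so genotype and phenotype randomness do not collide).
#' @return list with elements \code{pheno} (data.frame: id, phenotype and one
#'   column per fixed effect) and \code{truth} (list: qtlIndices, qtlEffects,
#'   trueBreedingValues, realizedH2, sigma2e).
#' @export
simulatePhenotypes <- function(geno, cfg) {
  stopifnot(is(geno, "GenotypeData"), is(cfg, "SimConfig"))
  if (cfg@h2 == 1 && cfg@nQtl == 0L)
    stop("degenerate config: h2 = 1 with no QTL has no genetic variance")
  set.seed(cfg@seed + 1000003L)
  n <- nIndividuals(geno)
  m <- nSnps(geno)
  d <- dosages(geno)

  qtl <- if (cfg@nQtl > 0L) sort(sample.int(m, cfg@nQtl)) else integer()
  if (length(qtl) && anyNA(d[, qtl]))
    stop("QTL columns must be complete (no missing dosages)")

  eff <- numeric(length(qtl))
  g <- numeric(n)
  if (length(qtl)) {
    eff <- rnorm(length(qtl))
    g0 <- as.numeric(d[, qtl, drop = FALSE] %*% eff)
    vg0 <- var(g0)
    scl <- if (cfg@h2 > 0 && vg0 > 0) sqrt(cfg@h2 / vg0) else 0
    eff <- eff * scl
    g <- as.numeric(d[, qtl, drop = FALSE] %*% eff)
  }

  e <- if (cfg@h2 < 1) rnorm(n, 0, sqrt(1 - cfg@h2)) else numeric(n)

  fixedPart <- numeric(n)
  covs <- list()
  for (f in names(cfg@fixedEffectLevels)) {
    nl <- cfg@fixedEffectLevels[[f]]
    lev <- sample.int(nl, n, replace = TRUE)
    le <- rnorm(nl, 0, cfg@fixedEffectSd)
    fixedPart <- fixedPart + le[lev]
    covs[[f]] <- factor(paste0(f, lev))
  }

  y <- fixedPart + g + e
  vge <- var(g + e)
  pheno <- data.frame(id = sampleIds(geno), phenotype = y,
                      stringsAsFactors = FALSE)
  for (f in names(covs)) pheno[[f]] <- covs[[f]]
  truth <- list(qtlIndices = qtl, qtlEffects = eff, trueBreedingValues = g,
                realizedH2 = if (vge > 0) var(g) / vge else 0,
                sigma2e = 1 - cfg@h2)
  list(pheno = pheno, truth = truth)
}

#' Mask a genotype matrix down to chip density
#'
#' Emulates a chip-versus-sequence design: keeps a uniform random subset of
#' SNPs (in genome order) as the "chip" panel and returns the full matrix as
#' truth, e.g. for exercising the imputation-concordance metric.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param keepFraction fraction of SNPs to keep, in (0, 1].
#' @param seed integer seed for the subset draw.
#' @return list(chip = masked \code{GenotypeData}, full = input).
#' @export
maskToChip <- function(geno, keepFraction, seed = 1L) {
  stopifnot(is(geno, "GenotypeData"))
  if (!is.numeric(keepFraction) || keepFraction <= 0 || keepFraction > 1)
    stop("keepFraction must be in (0, 1]")
  m <- nSnps(geno)
  set.seed(seed)
  keep <- sort(sample.int(m, max(1L, round(keepFraction * m))))
  if (keepFraction == 1) keep <- seq_len(m)
  list(chip = geno[, keep], full = geno)
}
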