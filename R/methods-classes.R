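#' Construct a simulation configuration
#'
#' Defaults describe the study conditions emulated throughout: 515
#' individuals, chip-scale marker counts spread over 18 autosomes, moderate
#' block LD, a sparse additive architecture, and the low heritabilities
#' typical of pig reproduction traits (defaults to 0.19).
#'
#' @param nIndividuals,nSnps,nChromosomes,ldBlockSize,withinBlockCorr
#'   population and LD-structure knobs; see \linkS4class{SimConfig}.
#' @param mafRange allele-frequency sampling range in (0, 0.5].
#' @param nQtl number of causal loci.
#' @param h2 target narrow-sense heritability.
#' @param fixedEffectLevels named integer vector of factor level counts.
#' @param fixedEffectSd SD of factor-level effects (phenotype units).
#' @param missingRate fraction of entries set missing (default 0).
#' @param seed integer seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nIndividuals = 100, nSnps = 500, seed = 7)
#' @export
simConfig <- function(nIndividuals = 515, nSnps = 10000, nChromosomes = 18,
                      ldBlockSize = 25, withinBlockCorr = 0.6,
                      mafRange = c(0.05, 0.5), nQtl = 100, h2 = 0.19,
                      fixedEffectLevels = c(year = 3L, month = 12L,
                                            litter_size = 8L),
                      fixedEffectSd = 0.5, missingRate = 0, seed = 1L) {
  new("SimConfig",
      nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
      nChromosomes = as.integer(nChromosomes),
      ldBlockSize = as.integer(ldBlockSize),
      withinBlockCorr = as.numeric(withinBlockCorr),
      mafRange = as.numeric(mafRange), nQtl = as.integer(nQtl),
      h2 = as.numeric(h2),
      fixedEffectLevels = setNames(as.integer(fixedEffectLevels),
                                   names(fixedEffectLevels)),
      fixedEffectSd = as.numeric(fixedEffectSd),
      missingRate = as.numeric(missingRate), seed = as.integer(seed))
}

#' Construct a GenotypeData object
#'
#' @param dosages individuals x SNPs matrix with entries 0/1/2/NA.
#' @param snpMeta data.frame with columns id, chrom, pos (and optionally
#'   a1, a2). A default metadata frame is built when omitted.
#' @param sampleIds character ids; defaults to rownames or ind_1..ind_n.
#' @return a validated \linkS4class{GenotypeData}.
#' @export
genotypeData <- function(dosages, snpMeta = NULL, sampleIds = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sampleIds)) {
    sampleIds <- if (!is.null(rownames(dosages))) rownames(dosages)
                 else paste0("ind_", seq_len(nrow(dosages)))
  }
  if (is.null(snpMeta)) {
    snpMeta <- data.frame(
      id = if (!is.null(colnames(dosages))) colnames(dosages)
           else paste0("snp_", seq_len(ncol(dosages))),
      chrom = "1", pos = seq_len(ncol(dosages)),
      a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  }
  if (!"a1" %in% names(snpMeta)) snpMeta$a1 <- "A"
  if (!"a2" %in% names(snpMeta)) snpMeta$a2 <- "G"
  rownames(dosages) <- sampleIds
  colnames(dosages) <- snpMeta$id
  new("GenotypeData", dosages = dosages, snpMeta = snpMeta,
      sampleIds = as.character(sampleIds))
}

#' @rdname GenotypeData-class
#' @aliases dosages,GenotypeData-method
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @rdname GenotypeData-class
setMethod("snpMeta", "GenotypeData", function(x) x@snpMeta)

#' @rdname GenotypeData-class
setMethod("sampleIds", "GenotypeData", function(x) x@sampleIds)

#' @rdname GenotypeData-class
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosages))

#' @rdname GenotypeData-class
setMethod("nIndividuals", "GenotypeData", function(x) nrow(x@dosages))

#' @rdname GenotypeData-class
#' @param i,j individual and SNP indices.
#' @param ... unused.
#' @param drop ignored; subsetting always returns a \code{GenotypeData}.
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  genotypeData(x@dosages[i, j, drop = FALSE],
               snpMeta = x@snpMeta[j, , drop = FALSE],
               sampleIds = x@sampleIds[i])
})

setMethod("show", "GenotypeData", function(object) {
  d <- object@dosages
  cat("GenotypeData:", nrow(d), "individuals x", ncol(d), "SNPs\n")
  cat("  chromosomes:", length(unique(object@snpMeta$chrom)),
      " missing rate:", signif(mean(is.na(d)), 3), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nIndividuals, "individuals,", object@nSnps,
      "SNPs on", object@nChromosomes, "chromosomes\n")
  cat("  LD blocks of", object@ldBlockSize, "SNPs, latent corr",
      object@withinBlockCorr, "; nQtl", object@nQtl, ", h2", object@h2,
      ", seed", object@seed, "\n")
})

#' @rdname GRMatrix-class
#' @aliases grmValues,GRMatrix-method
setMethod("grmValues", "GRMatrix", function(x) x@values)

#' @rdname GRMatrix-class
setMethod("grmWeights", "GRMatrix", function(x) x@weights)

#' @rdname GRMatrix-class
setMethod("sampleIds", "GRMatrix", function(x) x@sampleIds)

setMethod("show", "GRMatrix", function(object) {
  n <- nrow(object@values)
  cat("GRMatrix:", n, "x", n,
      if (is.null(object@weights)) "(uniform weights)" else "(weighted)", "\n")
  if (n) cat("  mean diagonal:", signif(mean(diag(object@values)), 4), "\n")
})

newGRMatrix <- function(values, sampleIds, weights = NULL) {
  dimnames(values) <- list(sampleIds, sampleIds)
  new("GRMatrix", values = values, sampleIds = as.character(sampleIds),
      weights = weights)
}
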