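#' @useDynLib pigGP, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats aov anova aggregate coef complete.cases cor cov dist
#'   ecdf lm model.matrix optim pchisq pf pgamma prcomp qf qnorm quantile
#'   rbeta rbinom rchisq rgamma rnorm runif sd setNames var dnorm pnorm
#' @importFrom utils head read.csv write.csv
NULL

#' Simulation configuration for synthetic genotype/phenotype data
#'
#' Holds the study conditions the synthetic-data generator emulates: a small
#' purebred pig population genotyped on a medium-density chip, with block-wise
#' linkage disequilibrium, a sparse additive QTL architecture, low
#' narrow-sense heritability, and categorical management fixed effects
#' (year, month, litter-size class).
#'
#' @slot nIndividuals number of individuals.
#' @slot nSnps number of biallelic autosomal SNPs.
#' @slot nChromosomes number of autosomes markers are spread over.
#' @slot ldBlockSize number of SNPs per LD block (blocks are independent).
#' @slot withinBlockCorr latent AR(1) correlation of adjacent SNPs within a
#'   block, in \[0, 1).
#' @slot mafRange length-2 numeric, allele-frequency sampling range in
#'   (0, 0.5].
#' @slot nQtl number of causal loci.
#' @slot h2 target narrow-sense heritability in \[0, 1\].
#' @slot fixedEffectLevels named integer vector, factor name -> number of
#'   levels.
#' @slot fixedEffectSd SD (phenotype units) of the level effects.
#' @slot missingRate fraction of dosages set missing (exercises QC; 0 by
#'   default).
#' @slot seed integer seed; equal seeds give bitwise-identical output.
#' @export
setClass("SimConfig", representation(
  nIndividuals = "integer", nSnps = "integer", nChromosomes = "integer",
  ldBlockSize = "integer", withinBlockCorr = "numeric", mafRange = "numeric",
  nQtl = "integer", h2 = "numeric", fixedEffectLevels = "integer",
  fixedEffectSd = "numeric", missingRate = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L || object@nSnps < 1L ||
      object@nChromosomes < 1L || object@ldBlockSize < 1L)
    msg <- c(msg, "dimensions must be positive")
  if (object@nQtl < 0L || object@nQtl > object@nSnps)
    msg <- c(msg, "nQtl must be in [0, nSnps]")
  if (object@h2 < 0 || object@h2 > 1) msg <- c(msg, "h2 must be in [0, 1]")
  if (object@withinBlockCorr < 0 || object@withinBlockCorr >= 1)
    msg <- c(msg, "withinBlockCorr must be in [0, 1)")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an increasing pair in (0, 0.5]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Individuals-by-SNPs dosage matrix with marker metadata
#'
#' The central genotype container: an n x m matrix of minor-allele dosages in
#' \{0, 1, 2, NA\}, per-SNP metadata (chromosome, position, alleles), and
#' sample identifiers. Positions are strictly increasing within each
#' chromosome.
#'
#' @slot dosages numeric matrix, individuals x SNPs, entries 0/1/2/NA.
#' @slot snpMeta data.frame with columns id, chrom, pos, a1, a2.
#' @slot sampleIds character vector of individual ids.
#' @export
setClass("GenotypeData", representation(
  dosages = "matrix", snpMeta = "data.frame", sampleIds = "character"
))

setValidity("GenotypeData", function(object) {
  d <- object@dosages
  msg <- character()
  if (nrow(d) != length(object@sampleIds))
    msg <- c(msg, "sampleIds length must equal nrow(dosages)")
  if (ncol(d) != nrow(object@snpMeta))
    msg <- c(msg, "snpMeta rows must equal ncol(dosages)")
  if (!all(c("id", "chrom", "pos") %in% names(object@snpMeta)))
    msg <- c(msg, "snpMeta must have columns id, chrom, pos")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  pos <- object@snpMeta$pos
  ok <- !is.na(pos)
  if (any(ok)) {
    sp <- split(pos[ok], object@snpMeta$chrom[ok])
    if (any(vapply(sp, function(x) any(diff(x) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Genomic relationship matrix
#'
#' Symmetric positive-semidefinite realized-kinship matrix computed from
#' centered marker dosages, optionally with per-SNP weights (prior-information
#' weighting). \code{weights} is NULL for the plain (uniform-weight) matrix.
#'
#' @slot values n x n symmetric numeric matrix.
#' @slot sampleIds character vector of individual ids (row/col names).
#' @slot weights per-SNP weight vector used to build the matrix, or NULL.
#' @export
setClass("GRMatrix", representation(
  values = "matrix", sampleIds = "character", weights = "ANY"
))

setValidity("GRMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (nrow(v) != length(object@sampleIds))
    msg <- c(msg, "sampleIds length must match matrix dimension")
  if (nrow(v) && max(abs(v - t(v))) > 1e-10)
    msg <- c(msg, "values must be symmetric to 1e-10")
  if (length(msg)) msg else TRUE
})
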