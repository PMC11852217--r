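#' Write genotypes in PLINK bed/bim/fam format
#'
#' SNP-major 2-bit encoding (magic bytes 0x6c 0x1b 0x01). Dosage codes count
#' copies of allele a1: 2 -> 00, het -> 10, 0 -> 11, missing -> 01, matching
#' the standard chip-data layout.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param prefix path prefix; writes prefix.bed/.bim/.fam.
#' @return invisibly, the prefix.
#' @export
writePlink <- function(geno, prefix) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosages(geno)
  meta <- snpMeta(geno)
  n <- nrow(d)
  m <- ncol(d)

  fam <- data.frame(fid = sampleIds(geno), iid = sampleIds(geno),
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = meta$chrom, id = meta$id, cm = 0L, pos = meta$pos,
                    a1 = meta$a1, a2 = meta$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  # per-dosage 2-bit codes at the four in-byte offsets
  code <- c(`2` = 0L, `NA` = 1L, `1` = 2L, `0` = 3L)
  nbytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * nbytes - n
  for (j in seq_len(m)) {
    v <- d[, j]
    cd <- integer(n)
    cd[is.na(v)] <- 1L
    cd[!is.na(v) & v == 2] <- 0L
    cd[!is.na(v) & v == 1] <- 2L
    cd[!is.na(v) & v == 0] <- 3L
    if (pad > 0) cd <- c(cd, rep(1L, pad))
    mat <- matrix(cd, nrow = 4L)
    bytes <- mat[1, ] + mat[2, ] * 4L + mat[3, ] * 16L + mat[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read genotypes from PLINK bed/bim/fam
#'
#' @param prefix path prefix of a SNP-major .bed/.bim/.fam triplet.
#' @return a \linkS4class{GenotypeData} with dosages counting allele a1.
#' @export
readPlink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  nbytes <- ceiling(n / 4)

  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file")
  raw <- readBin(con, "raw", nbytes * m)
  if (length(raw) < nbytes * m) stop("truncated bed file")

  b <- as.integer(raw)
  # decode the four 2-bit fields of every byte at once
  q <- cbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  dose <- c(2, NA, 1, 0)[t(q) + 1L]           # length 4*nbytes*m, SNP-major
  dose <- matrix(dose, nrow = 4L * nbytes)[seq_len(n), , drop = FALSE]

  meta <- data.frame(id = as.character(bim$V2), chrom = as.character(bim$V1),
                     pos = bim$V4, a1 = as.character(bim$V5),
                     a2 = as.character(bim$V6), stringsAsFactors = FALSE)
  genotypeData(dose, snpMeta = meta, sampleIds = as.character(fam$V2))
}

#' @importFrom utils read.table write.table
NULL

#' Write the phenotype/covariate table and the simulation truth
#'
#' Companions to \code{\link{writePlink}} for a fully file-based handoff:
#' the phenotype table goes to CSV and the trait truth (QTL indices, effects,
#' breeding values, realized heritability) to JSON.
#'
#' @param pheno data.frame as returned by \code{\link{simulatePhenotypes}}.
#' @param truth truth list as returned by \code{\link{simulatePhenotypes}}.
#' @param phenoFile,truthFile output paths.
#' @return invisibly, NULL.
#' @export
writePhenoTruth <- function(pheno, truth, phenoFile, truthFile) {
  write.csv(pheno, phenoFile, row.names = FALSE)
  jsonlite::write_json(truth, truthFile, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Write a GRM as a GCTA-style text triplet plus id file
#'
#' Lower-triangle triplet layout (i, j, nSnps, value) in prefix.grm.txt and
#' the two-column family/individual id file in prefix.grm.id.
#'
#' @param grm a \linkS4class{GRMatrix}.
#' @param prefix output path prefix.
#' @param nSnpsUsed marker count recorded in the third column.
#' @return invisibly, the prefix.
#' @export
writeGctaGrm <- function(grm, prefix, nSnpsUsed = NA_integer_) {
  v <- grmValues(grm)
  n <- nrow(v)
  ij <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  trip <- data.frame(i = ij[, 1], j = ij[, 2], n = nSnpsUsed,
                     value = v[ij])
  write.table(trip, paste0(prefix, ".grm.txt"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(fid = sampleIds(grm), iid = sampleIds(grm)),
              paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
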