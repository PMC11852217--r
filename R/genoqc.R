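#' QC thresholds for chip-style SNP filtering
#'
#' @param minCallRate minimum per-SNP call rate (default 0.95).
#' @param minMaf minimum minor allele frequency (default 0.01).
#' @param hweAlpha Hardy-Weinberg chi-square p-value floor (default 1e-6).
#' @return list of class \code{qcThresholds}.
#' @export
qcThresholds <- function(minCallRate = 0.95, minMaf = 0.01,
                         hweAlpha = 1e-6) {
  stopifnot(minCallRate > 0, minCallRate < 1 || minCallRate == 1,
            minMaf >= 0, minMaf < 1, hweAlpha > 0, hweAlpha < 1)
  structure(list(minCallRate = minCallRate, minMaf = minMaf,
                 hweAlpha = hweAlpha), class = "qcThresholds")
}

#' Per-SNP call rate, minor allele frequency and HWE test
#'
#' MAF is min(f, 1 - f) with f the allele frequency among non-missing calls;
#' the HWE p-value comes from the 1-df chi-square of observed vs expected
#' genotype counts (the usual chip-QC test at these sample sizes; monomorphic
#' or all-missing SNPs get NA flagged rather than a value).
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @return data.frame: id, callRate, maf, hweP, monomorphic.
#' @export
snpSummary <- function(geno) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosages(geno)
  if (nrow(d) < 2) stop("need at least 2 individuals")
  nObs <- colSums(!is.na(d))
  callRate <- nObs / nrow(d)
  f <- colMeans(d, na.rm = TRUE) / 2
  f[nObs == 0] <- NA_real_
  maf <- pmin(f, 1 - f)

  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  e0 <- nObs * (1 - f)^2
  e1 <- nObs * 2 * f * (1 - f)
  e2 <- nObs * f^2
  chi2 <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  hweP <- pchisq(chi2, df = 1, lower.tail = FALSE)
  mono <- !is.na(f) & (f == 0 | f == 1)
  hweP[mono | nObs == 0] <- NA_real_
  maf[nObs == 0] <- NA_real_
  data.frame(id = snpMeta(geno)$id, callRate = callRate, maf = maf,
             hweP = hweP, monomorphic = mono | nObs == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a QC removal ledger
#'
#' Bookkeeping of staged SNP removals: \code{final = initial - sum(removals)}
#' is enforced at construction, so ledger arithmetic can never drift from the
#' filtering it describes.
#'
#' @param initial SNP count before filtering.
#' @param removedByStage named integer vector, stage -> count removed.
#' @return list of class \code{qcLedger} with fields initialSnps,
#'   removedByStage, finalSnps.
#' @export
qcLedger <- function(initial, removedByStage) {
  removedByStage <- setNames(as.integer(removedByStage),
                             names(removedByStage))
  if (any(removedByStage < 0)) stop("stage removals must be non-negative")
  final <- as.integer(initial) - sum(removedByStage)
  if (final < 0) stop("removals exceed the initial SNP count")
  structure(list(initialSnps = as.integer(initial),
                 removedByStage = removedByStage, finalSnps = final),
            class = "qcLedger")
}

#' @export
print.qcLedger <- function(x, ...) {
  cat("SNP QC ledger: initial", x$initialSnps, "\n")
  for (s in names(x$removedByStage))
    cat(sprintf("  - %-28s %d removed\n", s, x$removedByStage[[s]]))
  cat("  final", x$finalSnps, "\n")
  invisible(x)
}

#' Apply staged SNP quality control
#'
#' Stages in fixed order: (1) SNPs without positional information or on sex
#' chromosomes; (2) call rate; (3) MAF (computed among non-missing calls,
#' PLINK-like); (4) HWE chi-square. Returns the filtered matrix plus a
#' \code{\link{qcLedger}} recording each stage's removals. Running the filter
#' twice removes nothing the second time.
#'
#' @param geno a \linkS4class{GenotypeData} with snpMeta present.
#' @param thr a \code{\link{qcThresholds}}.
#' @param sexChroms chromosome labels treated as sex chromosomes.
#' @return list(geno = filtered \code{GenotypeData}, ledger = qcLedger).
#' @export
applyQc <- function(geno, thr = qcThresholds(),
                    sexChroms = c("X", "Y", "19", "20")) {
  stopifnot(is(geno, "GenotypeData"), inherits(thr, "qcThresholds"))
  meta <- snpMeta(geno)
  m0 <- nSnps(geno)

  badPos <- is.na(meta$pos) | meta$pos <= 0 | meta$chrom %in% sexChroms
  g <- geno[, !badPos]

  st <- snpSummary(g)
  lowCall <- st$callRate < thr$minCallRate
  g2 <- g[, !lowCall]

  st2 <- snpSummary(g2)
  lowMaf <- is.na(st2$maf) | st2$maf < thr$minMaf
  g3 <- g2[, !lowMaf]

  st3 <- snpSummary(g3)
  badHwe <- !is.na(st3$hweP) & st3$hweP < thr$hweAlpha
  g4 <- g3[, !badHwe]

  if (nSnps(g4) == 0L) stop("QC removed every SNP")
  led <- qcLedger(m0, c(no_position_or_sex_chrom = sum(badPos),
                        call_rate = sum(lowCall), maf = sum(lowMaf),
                        hwe = sum(badHwe)))
  list(geno = g4, ledger = led)
}

#' Imputation concordance against sequenced truth
#'
#' Per-SNP accuracy is the fraction of subset individuals whose dosage in the
#' imputed matrix equals the truth at that locus (identical 0/1/2 dosage; a
#' missing imputed call counts as a mismatch). SNPs are additionally binned at
#' the accuracy thresholds 0.3, 0.6 and 0.9, and loci at accuracy exactly 1
#' are flagged for retention.
#'
#' @param imputed,truth \linkS4class{GenotypeData} objects sharing a SNP set.
#' @param samples ids of the comparison subset (default: all shared ids).
#' @param thresholds accuracy bin thresholds.
#' @return list of class \code{concordanceReport}: perSnpAccuracy (named),
#'   meanAccuracy, bins (data.frame threshold/n/min/max/mean), perfectSnps.
#' @export
imputationConcordance <- function(imputed, truth, samples = NULL,
                                  thresholds = c(0.3, 0.6, 0.9)) {
  stopifnot(is(imputed, "GenotypeData"), is(truth, "GenotypeData"))
  if (!identical(sort(snpMeta(imputed)$id), sort(snpMeta(truth)$id)))
    stop("imputed and truth matrices must share the same SNP set")
  if (is.null(samples)) samples <- intersect(sampleIds(imputed),
                                             sampleIds(truth))
  if (!length(samples)) stop("no shared individuals to compare")
  di <- dosages(imputed)[match(samples, sampleIds(imputed)),
                         order(snpMeta(imputed)$id), drop = FALSE]
  dt <- dosages(truth)[match(samples, sampleIds(truth)),
                       order(snpMeta(truth)$id), drop = FALSE]
  match_ <- !is.na(dt) & !is.na(di) & di == dt
  acc <- colSums(match_) / nrow(di)
  names(acc) <- colnames(di)
  bins <- do.call(rbind, lapply(thresholds, function(t) {
    a <- acc[acc >= t]
    data.frame(threshold = t, n = length(a),
               min = if (length(a)) min(a) else NA_real_,
               max = if (length(a)) max(a) else NA_real_,
               mean = if (length(a)) mean(a) else NA_real_)
  }))
  structure(list(perSnpAccuracy = acc, meanAccuracy = mean(acc),
                 bins = bins, perfectSnps = names(acc)[acc == 1]),
            class = "concordanceReport")
}

#' @export
print.concordanceReport <- function(x, ...) {
  cat("concordanceReport:", length(x$perSnpAccuracy), "SNPs, mean accuracy",
      signif(x$meanAccuracy, 4), ";", length(x$perfectSnps),
      "loci at accuracy 1\n")
  invisible(x)
}
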