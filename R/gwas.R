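#' PCA of the standardized dosage matrix
#'
#' Missing dosages are mean-imputed, columns centered and scaled to unit
#' variance (zero-variance SNPs are dropped from the decomposition), and the
#' spectrum obtained from the n x n crossproduct. Component p-values come
#' from \code{\link{eigenSignificance}}; components with p < \code{alpha} are
#' flagged for use as association covariates.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param k number of leading components to return scores/p-values for
#'   (default 30).
#' @param alpha selection threshold on the component p-value (default 0.01).
#' @return list of class \code{pcaResult}: scores (n x k), eigenvalues
#'   (descending, all), pvalues (length k), selected (indices with
#'   p < alpha), k.
#' @export
computePca <- function(geno, k = 30, alpha = 0.01) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosages(geno)
  n <- nrow(d)
  if (k > min(n, ncol(d))) stop("k exceeds min(n, m)")
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d))
  if (length(idx)) d[idx] <- mu[(idx - 1) %/% n + 1]
  sds <- apply(d, 2, sd)
  keep <- sds > 0
  Xs <- scale(d[, keep, drop = FALSE])
  m <- ncol(Xs)
  eg <- eigen(tcrossprod(Xs) / m, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  scores <- eg$vectors %*% diag(sqrt(vals * m), n, n)
  rownames(scores) <- sampleIds(geno)
  pv <- eigenSignificance(vals, k = k)
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 eigenvalues = vals, pvalues = pv$p,
                 twStats = pv$twStat, selected = which(pv$p < alpha),
                 k = k), class = "pcaResult")
}

#' Tracy-Widom significance of leading eigenvalues
#'
#' Successive testing in the EIGENSTRAT style: for the j-th component the
#' trailing spectrum (eigenvalues j..end) is renormalized, an effective
#' marker count estimated from its first two moments, and the leading value
#' mapped to the Tracy-Widom (beta = 1) scale. Each component is tested
#' against its own null; p-values are not forced monotone.
#'
#' @param eigenvalues non-negative eigenvalues in descending order (zero
#'   eigenvalues from centering are trimmed automatically).
#' @param k how many leading components to test.
#' @return data.frame: component, twStat, p.
#' @export
eigenSignificance <- function(eigenvalues, k = length(eigenvalues) - 1L) {
  ev <- eigenvalues[eigenvalues > 1e-10 * max(eigenvalues)]
  if (length(ev) < 2) stop("need at least 2 positive eigenvalues")
  k <- min(k, length(ev) - 1L)
  tw <- p <- numeric(k)
  for (j in seq_len(k)) {
    s <- ev[j:length(ev)]
    mm <- length(s)
    # moment estimator of the effective marker count, exact in expectation
    # for a null Wishart spectrum (E[S1] = mn, E[S2] = mn(m+n+1)); the tested
    # eigenvalue is left out so its own fluctuation does not self-normalize
    sr <- s[-1]
    m2 <- mm - 1
    s1r <- sum(sr)
    s2r <- sum(sr^2)
    neff <- ((m2 + 1) * s1r^2) / (m2 * s2r - s1r^2)
    l <- mm * s[1] / sum(s)
    if (m2 < 2 || !is.finite(neff) || neff <= 1) {
      tw[j] <- NA_real_
      p[j] <- NA_real_
      next
    }
    a <- sqrt(neff - 1)
    b <- sqrt(mm)
    mu <- (a + b)^2 / neff
    sig <- ((a + b) / neff) * (1 / a + 1 / b)^(1 / 3)
    tw[j] <- (l - mu) / sig
    p[j] <- ptw1(tw[j], lower.tail = FALSE)
  }
  data.frame(component = seq_len(k), twStat = tw, p = p)
}

#' Tracy-Widom (beta = 1) distribution function
#'
#' Shifted-gamma approximation (shape 46.446, scale 0.18605, shift 9.84801),
#' accurate to about 1e-3 in the CDF over the range relevant for component
#' selection.
#'
#' @param q quantile.
#' @param lower.tail as in other p-functions.
#' @return probability.
#' @export
ptw1 <- function(q, lower.tail = TRUE) {
  pgamma(q + 9.84801210848, shape = 46.44604884, scale = 0.18605402228,
         lower.tail = lower.tail)
}

#' Single-SNP association scan with covariates
#'
#' Per SNP, an ordinary least-squares fit of yc on dosage + covariates +
#' intercept, computed by projecting trait and dosages off the covariate
#' space once and regressing residual on residual (algebraically identical to
#' the joint fit). Missing dosages are mean-imputed. Monomorphic SNPs are
#' reported with beta = 0, p = 1 and flagged.
#'
#' @param yc corrected, standardized trait values.
#' @param geno a \linkS4class{GenotypeData} aligned with \code{yc}.
#' @param covariates optional numeric matrix (e.g. selected PC scores).
#' @return data.frame of class \code{gwasResult}: id, chrom, pos, freq,
#'   beta, se, t, p, monomorphic.
#' @export
singleSnpAssoc <- function(yc, geno, covariates = NULL) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosages(geno)
  n <- nrow(d)
  if (length(yc) != n) stop("yc length must match individuals")
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d))
  if (length(idx)) d[idx] <- mu[(idx - 1) %/% n + 1]

  C <- cbind(rep(1, n), covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("covariate matrix is rank deficient")
  yr <- qr.resid(qrC, yc)
  Xr <- qr.resid(qrC, d)

  sxx <- colSums(Xr^2)
  mono <- sxx < 1e-12
  sxx[mono] <- 1
  beta <- colSums(Xr * yr) / sxx
  dfres <- n - ncol(C) - 1L
  rss <- sum(yr^2) - beta^2 * sxx
  rss[rss < 0] <- 0
  se <- sqrt(rss / dfres / sxx)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), dfres, lower.tail = FALSE)
  beta[mono] <- 0
  se[mono] <- NA_real_
  tstat[mono] <- 0
  pval[mono] <- 1
  meta <- snpMeta(geno)
  out <- data.frame(id = meta$id, chrom = meta$chrom, pos = meta$pos,
                    freq = mu / 2, beta = beta, se = se, t = tstat, p = pval,
                    monomorphic = mono, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("gwasResult", "data.frame")
  out
}

#' Per-SNP proportion of phenotypic variance explained
#'
#' pve_j = 2 f_j (1 - f_j) beta_j^2 / Var(yc), clipped to \[0, 1\]; the
#' marginal OLS effect is used (and labeled as such).
#'
#' @param beta per-SNP allele-substitution effects (yc units per allele).
#' @param freq allele frequencies in (0, 1) (monomorphic loci give 0).
#' @param varYc phenotypic variance of the corrected trait (positive).
#' @return numeric pve vector in \[0, 1\].
#' @export
snpPve <- function(beta, freq, varYc) {
  if (!is.numeric(varYc) || varYc <= 0) stop("varYc must be positive")
  pmin(pmax(2 * freq * (1 - freq) * beta^2 / varYc, 0), 1)
}

#' Select genome-wide significant loci
#'
#' @param assoc a \code{gwasResult}.
#' @param alpha significance threshold (default 1e-5).
#' @return integer indices into \code{assoc}, sorted by ascending p.
#' @export
selectSignificant <- function(assoc, alpha = 1e-5) {
  idx <- which(assoc$p < alpha)
  idx[order(assoc$p[idx])]
}

#' Build nested GWAS-ranked SNP density panels
#'
#' SNPs are ranked by ascending association p-value with ties broken by
#' genome order (chromosome, then position); the panel of size s is the
#' top-s ranked set, so panels of increasing size are nested by
#' construction. Panel indices are reported in inclusion-rank order.
#'
#' @param assoc a \code{gwasResult}.
#' @param sizes ascending panel sizes, max at most the number of SNPs.
#' @return named list of \code{panelSpec} lists (name, snpIndices, size).
#' @export
buildPanels <- function(assoc, sizes) {
  m <- nrow(assoc)
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be ascending")
  if (max(sizes) > m) stop("panel size exceeds the number of SNPs")
  chromNum <- suppressWarnings(as.numeric(assoc$chrom))
  chromKey <- ifelse(is.na(chromNum), 1e6 + as.numeric(factor(assoc$chrom)),
                     chromNum)
  rank <- order(assoc$p, chromKey, assoc$pos)
  out <- lapply(sizes, function(s) {
    structure(list(name = paste0("panel_", s),
                   snpIndices = rank[seq_len(s)], size = s),
              class = "panelSpec")
  })
  names(out) <- paste0("panel_", sizes)
  out
}

#' Write an association scan as PLINK-assoc-like TSV
#'
#' @param assoc a \code{gwasResult} (optionally with a pve column).
#' @param file output path.
#' @return invisibly, NULL.
#' @export
writeGwas <- function(assoc, file) {
  write.table(assoc, file, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(NULL)
}
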