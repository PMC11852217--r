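# Small in-code fixtures shared across test files.

# GenotypeData from a plain dosage matrix with default metadata
makeGeno <- function(d, chrom = NULL, pos = NULL) {
  d <- as.matrix(d)
  meta <- data.frame(
    id = paste0("s", seq_len(ncol(d))),
    chrom = if (is.null(chrom)) rep("1", ncol(d)) else as.character(chrom),
    pos = if (is.null(pos)) seq_len(ncol(d)) else pos,
    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  genotypeData(d, snpMeta = meta)
}

# independent-SNP genotypes: binomial(2, f) draws, no LD
makeNullGeno <- function(n, m, fRange = c(0.1, 0.5), seed = 1) {
  set.seed(seed)
  f <- runif(m, fRange[1], fRange[2])
  d <- matrix(rbinom(n * m, 2, rep(f, each = n)), n, m)
  makeGeno(d)
}

# brute-force OLS oracle: normal-equation solve on an explicit design
olsOracle <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  e <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(e^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tt <- b / se
  list(b = as.numeric(b), se = as.numeric(se), t = as.numeric(tt),
       p = 2 * pt(abs(as.numeric(tt)), df, lower.tail = FALSE),
       e = as.numeric(e))
}
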