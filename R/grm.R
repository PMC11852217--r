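#' VanRaden (method 1) genomic relationship matrix
#'
#' G = Z Z' / (2 sum f_j (1 - f_j)) with Z the dosage matrix centered at
#' twice the observed allele frequency. Monomorphic SNPs carry no
#' information for the denominator and are excluded with a warning; missing
#' dosages are mean-imputed (equivalently, centered to zero).
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @return a \linkS4class{GRMatrix} with uniform weights.
#' @export
vanRadenGrm <- function(geno) {
  weightedGrm(geno, weights = NULL)
}

#' Prior-information SNP weights
#'
#' The weighted set (QTL-interval loci plus GWAS-significant loci) receives
#' weights proportional to per-SNP phenotypic variance explained, rescaled so
#' that the weighted set's share of the heterozygosity-weighted total
#' sum(w_j * 2 f_j (1 - f_j)) equals \code{omega}; all remaining SNPs share
#' the complement 1 - omega uniformly. With omega = 0.7 the weighted loci
#' dominate the relationship matrix without silencing the genomic background.
#'
#' @param pve per-SNP variance-explained fractions (length m).
#' @param weightedSet integer indices of the weighted (prior) loci.
#' @param freq per-SNP allele frequencies (length m).
#' @param omega weighted set's target share of the matrix, in (0, 1);
#'   default 0.7.
#' @return numeric weight vector of length m.
#' @export
assignWeights <- function(pve, weightedSet, freq, omega = 0.7) {
  m <- length(pve)
  if (length(freq) != m) stop("pve and freq lengths differ")
  if (!is.numeric(omega) || omega <= 0 || omega >= 1)
    stop("omega must be in (0, 1)")
  weightedSet <- unique(as.integer(weightedSet))
  if (!length(weightedSet)) stop("empty weighted set with omega > 0")
  if (any(weightedSet < 1 | weightedSet > m)) stop("weightedSet out of range")
  h <- 2 * freq * (1 - freq)
  total <- sum(h)
  inW <- seq_len(m) %in% weightedSet
  sw <- sum(pve[inW] * h[inW])
  if (sw <= 0) stop("weighted set has zero total variance explained")
  w <- numeric(m)
  w[inW] <- pve[inW] * (omega * total / sw)
  hOut <- sum(h[!inW])
  if (hOut > 0) w[!inW] <- (1 - omega) * total / hOut
  w
}

#' Weighted genomic relationship matrix
#'
#' G_w = Z D Z' / sum(w_j * 2 f_j (1 - f_j)), D = diag(weights). Uniform
#' weights reproduce \code{\link{vanRadenGrm}} exactly, a zero weight is
#' equivalent to dropping the SNP, and rescaling all weights by a constant
#' leaves the matrix unchanged.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param weights non-negative per-SNP weights (NULL for uniform).
#' @return a \linkS4class{GRMatrix}.
#' @export
weightedGrm <- function(geno, weights = NULL) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosages(geno)
  n <- nrow(d)
  uniform <- is.null(weights)
  if (uniform) weights <- rep(1, ncol(d))
  if (length(weights) != ncol(d)) stop("one weight per SNP required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("weights must not all be zero")

  f <- colMeans(d, na.rm = TRUE) / 2
  mono <- f <= 0 | f >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from the GRM")
    d <- d[, !mono, drop = FALSE]
    f <- f[!mono]
    weights <- weights[!mono]
  }
  if (!ncol(d)) stop("no polymorphic SNPs left")
  Z <- sweep(d, 2L, 2 * f, "-")
  Z[is.na(Z)] <- 0
  denom <- sum(weights * 2 * f * (1 - f))
  Zs <- sweep(Z, 2L, sqrt(weights), "*")
  G <- tcrossprod(Zs) / denom
  G <- (G + t(G)) / 2
  newGRMatrix(G, sampleIds(geno), weights = if (uniform) NULL else weights)
}

#' Single-component AI-REML heritability estimation
#'
#' REML for yc = mu + g + e with g ~ N(0, G sigma2_g), e ~ N(0, I sigma2_e),
#' using average-information updates with an EM fallback whenever an AI step
#' leaves the parameter space, convergence at |delta logL| < tol. One
#' eigendecomposition of G reduces every iteration to O(n) work. The SE of
#' h2 = sigma2_g / (sigma2_g + sigma2_e) comes from the inverse AI matrix by
#' the delta method.
#'
#' @param grm a \linkS4class{GRMatrix} (PSD up to tolerance).
#' @param y trait values (length n).
#' @param maxIter maximum iterations (default 100).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @return list(h2, se, sigma2g, sigma2e, logLik, iterations, converged,
#'   trajectory).
#' @export
remlH2 <- function(grm, y, maxIter = 100, tol = 1e-6) {
  stopifnot(is(grm, "GRMatrix"))
  G <- grmValues(grm)
  n <- length(y)
  if (nrow(G) != n) stop("GRM dimension must match y")
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("GRM is not PSD within tolerance")
  lam <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(eg$vectors, y))
  xt <- as.numeric(crossprod(eg$vectors, rep(1, n)))

  vp <- var(y)
  sg <- se_ <- vp / 2
  floorv <- 1e-8 * vp

  compute <- function(sg, se_) {
    dd <- pmax(sg * lam + se_, 1e-12 * vp)
    xVx <- sum(xt^2 / dd)
    xVy <- sum(xt * yt / dd)
    Pv <- function(v) v / dd - (xt / dd) * (sum(xt * v / dd) / xVx)
    Py <- Pv(yt)
    ll <- -0.5 * (sum(log(dd)) + log(xVx) + sum(yt * Py))
    trPA <- function(a) sum(a / dd) - sum(xt^2 * a / dd^2) / xVx
    scoreG <- -0.5 * (trPA(lam) - sum(Py * lam * Py))
    scoreE <- -0.5 * (trPA(rep(1, n)) - sum(Py^2))
    ug <- lam * Py
    ue <- Py
    AI <- 0.5 * matrix(c(sum(ug * Pv(ug)), sum(ug * Pv(ue)),
                         sum(ug * Pv(ue)), sum(ue * Pv(ue))), 2, 2)
    list(ll = ll, score = c(scoreG, scoreE), AI = AI)
  }

  st <- compute(sg, se_)
  traj <- st$ll
  conv <- FALSE
  iters <- 0L
  for (it in seq_len(maxIter)) {
    iters <- it
    step <- tryCatch(solve(st$AI, st$score), error = function(e) NULL)
    newPar <- if (is.null(step)) c(-1, -1) else c(sg, se_) + step
    if (!is.null(step) && (any(!is.finite(newPar)) || any(newPar <= 0))) {
      # step-halve the AI direction back into the parameter space
      a <- 0.5
      for (h in 1:30) {
        newPar <- c(sg, se_) + a * step
        if (all(is.finite(newPar)) && all(newPar > 0)) break
        a <- a / 2
      }
    }
    if (any(!is.finite(newPar)) || any(newPar <= 0)) {
      # EM fallback: sigma^2_new = sigma^2 + 2 sigma^4 score / n
      newPar <- c(sg + 2 * sg^2 * st$score[1] / n,
                  se_ + 2 * se_^2 * st$score[2] / n)
    }
    newPar <- pmax(newPar, floorv)
    newSt <- compute(newPar[1], newPar[2])
    if (!is.finite(newSt$ll)) stop("REML failed to evaluate; trajectory: ",
                                   paste(signif(traj, 6), collapse = ", "))
    sg <- newPar[1]
    se_ <- newPar[2]
    delta <- abs(newSt$ll - st$ll)
    st <- newSt
    traj <- c(traj, st$ll)
    if (delta < tol) { conv <- TRUE; break }
  }
  if (!conv) stop("REML did not converge in ", maxIter,
                  " iterations; logL trajectory: ",
                  paste(signif(traj, 6), collapse = ", "))
  h2 <- sg / (sg + se_)
  V <- tryCatch(solve(st$AI), error = function(e) matrix(NA_real_, 2, 2))
  gr <- c(se_, -sg) / (sg + se_)^2
  seH2 <- sqrt(max(as.numeric(t(gr) %*% V %*% gr), 0))
  list(h2 = h2, se = seH2, sigma2g = sg, sigma2e = se_, logLik = st$ll,
       iterations = iters, converged = conv, trajectory = traj)
}
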