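#' Fit GBLUP through the mixed-model equations
#'
#' y = 1 mu + g + e with g ~ N(0, G sigma2_g), e ~ N(0, I sigma2_e). The
#' breeding values solve g = G (G + lambda I)^-1 (y - 1 mu) with
#' lambda = sigma2_e / sigma2_g; mu is the GLS mean (or 0 when
#' \code{estimateMu = FALSE}, e.g. for pre-centered traits). Variance
#' components default to an AI-REML fit on the training data. When the
#' system is numerically singular a small ridge stabilizes the solve, with a
#' warning.
#'
#' @param grm training \linkS4class{GRMatrix}.
#' @param y training trait values.
#' @param sigma2g,sigma2e variance components; both NULL triggers
#'   \code{\link{remlH2}}.
#' @param estimateMu estimate the overall mean by GLS? (default TRUE)
#' @return object of class \code{gblupFit}: mu, gebv, fitted, alpha
#'   (the (G + lambda I)^-1 (y - mu) weights used for prediction), lambda,
#'   sigma2g, sigma2e, trainIds.
#' @export
fitGblup <- function(grm, y, sigma2g = NULL, sigma2e = NULL,
                     estimateMu = TRUE) {
  stopifnot(is(grm, "GRMatrix"))
  G <- grmValues(grm)
  n <- length(y)
  if (nrow(G) != n) stop("GRM dimension must match y")
  if (is.null(sigma2g) || is.null(sigma2e)) {
    vc <- remlH2(grm, y)
    sigma2g <- vc$sigma2g
    sigma2e <- vc$sigma2e
  }
  if (sigma2g <= 0) stop("sigma2g must be positive")
  lambda <- sigma2e / sigma2g
  A <- G + diag(lambda, n)
  mu <- 0
  Ainv_y <- tryCatch(solve(A, y), error = function(e) NULL)
  if (is.null(Ainv_y)) {
    warning("singular GBLUP system; ridge-stabilized solve")
    A <- A + diag(1e-6 * mean(diag(G)), n)
    Ainv_y <- solve(A, y)
  }
  if (estimateMu) {
    one <- rep(1, n)
    Ainv_1 <- solve(A, one)
    mu <- sum(one * Ainv_y) / sum(one * Ainv_1)
  }
  alpha <- solve(A, y - mu)
  gebv <- as.numeric(G %*% alpha)
  structure(list(mu = mu, gebv = gebv, fitted = mu + gebv, alpha = alpha,
                 lambda = lambda, sigma2g = sigma2g, sigma2e = sigma2e,
                 trainIds = sampleIds(grm)),
            class = "gblupFit")
}

#' Predict breeding values for new individuals from a GBLUP fit
#'
#' @param object a \code{gblupFit}.
#' @param gCross relationship block G\[new, train\] (columns in training
#'   order), or a joint \linkS4class{GRMatrix} from which the block is
#'   extracted by id.
#' @param newIds ids of the prediction individuals when \code{gCross} is a
#'   joint GRM.
#' @param ... unused.
#' @return predicted trait values mu + G_new,train alpha.
#' @export
predict.gblupFit <- function(object, gCross, newIds = NULL, ...) {
  if (is(gCross, "GRMatrix")) {
    if (is.null(newIds)) stop("newIds required with a joint GRM")
    v <- grmValues(gCross)
    ri <- match(newIds, sampleIds(gCross))
    ci <- match(object$trainIds, sampleIds(gCross))
    if (anyNA(ri) || anyNA(ci)) stop("ids missing from the joint GRM")
    gCross <- v[ri, ci, drop = FALSE]
  }
  if (ncol(gCross) != length(object$alpha))
    stop("gCross columns must match the training set")
  as.numeric(object$mu + gCross %*% object$alpha)
}

#' @export
print.gblupFit <- function(x, ...) {
  cat("gblupFit:", length(x$gebv), "individuals, lambda =",
      signif(x$lambda, 4), "(h2 =",
      signif(x$sigma2g / (x$sigma2g + x$sigma2e), 3), ")\n")
  invisible(x)
}
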