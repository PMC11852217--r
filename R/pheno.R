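#' Fit the fixed-effect correction model and return residuals
#'
#' Least-squares fit of the raw trait on management fixed effects
#' (y = Xb + e): the residual e carries the genetic signal forward. Factors
#' enter as treatment-coded categorical effects; numeric covariates enter
#' linearly. A rank-deficient design aborts with the name of the offending
#' column rather than silently dropping it.
#'
#' @param tab data.frame with one row per individual.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (possibly
#'   empty for an intercept-only fit, in which case e = y - mean(y)).
#' @return numeric residual vector, named by \code{tab$id} when present.
#' @export
fitCorrectionModel <- function(tab, trait, covariates = NULL) {
  stopifnot(is.data.frame(tab), trait %in% names(tab))
  if (length(covariates) && !all(covariates %in% names(tab)))
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(tab)), collapse = ", "))
  use <- c(trait, covariates)
  if (any(!complete.cases(tab[, use, drop = FALSE])))
    stop("covariates and trait must be non-missing for modeled rows")
  fml <- if (length(covariates))
    stats::reformulate(covariates, response = trait) else
    stats::as.formula(paste(trait, "~ 1"))
  fit <- lm(fml, data = tab)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  e <- stats::residuals(fit)
  if ("id" %in% names(tab)) names(e) <- tab$id
  e
}

#' Remove aberrant residuals by an SD-unit threshold
#'
#' Drops records whose residual deviates from the residual mean by more than
#' \code{rule} sample SDs. Applied once by default; \code{iterate = TRUE}
#' recomputes mean/SD after each pass until no further removals.
#'
#' @param e numeric residuals.
#' @param rule positive threshold in SD units (default 3).
#' @param iterate repeat until stable?
#' @return list(residuals, keep = logical over the input, nRemoved,
#'   removalRule).
#' @export
removeAberrant <- function(e, rule = 3, iterate = FALSE) {
  if (!is.numeric(rule) || rule <= 0) stop("rule must be positive")
  keep <- rep(TRUE, length(e))
  repeat {
    cur <- e[keep]
    s <- sd(cur)
    if (!is.finite(s) || s == 0) break  # no spread: nothing is aberrant
    out <- keep & abs(e - mean(cur)) > rule * s
    if (!any(out)) break
    keep[out] <- FALSE
    if (all(!keep)) stop("aberrant-record rule removed every record")
    if (!iterate) break
  }
  if (all(!keep)) stop("aberrant-record rule removed every record")
  list(residuals = e[keep], keep = keep, nRemoved = sum(!keep),
       removalRule = sprintf("|e - mean| > %g SD%s", rule,
                             if (iterate) " (iterated)" else ""))
}

#' Standardize residuals to zero mean and unit (n-1) SD
#'
#' @param e numeric residuals with positive spread.
#' @return the standardized vector yc.
#' @export
standardizeResiduals <- function(e) {
  s <- sd(e)
  if (!is.finite(s) || s == 0) stop("zero residual variance")
  (e - mean(e)) / s
}

#' Phenotype-correction pipeline: fit, filter, standardize
#'
#' Convenience wrapper chaining \code{\link{fitCorrectionModel}},
#' \code{\link{removeAberrant}} and \code{\link{standardizeResiduals}} into
#' the corrected, standardized trait vector yc used by every downstream
#' predictor.
#'
#' @inheritParams fitCorrectionModel
#' @inheritParams removeAberrant
#' @return object of class \code{correctedPhenotype}: list(sampleIds, yc,
#'   nRemoved, removalRule).
#' @export
correctPhenotypes <- function(tab, trait = "phenotype", covariates = NULL,
                              rule = 3, iterate = FALSE) {
  e <- fitCorrectionModel(tab, trait, covariates)
  flt <- removeAberrant(e, rule = rule, iterate = iterate)
  yc <- standardizeResiduals(flt$residuals)
  structure(list(sampleIds = names(flt$residuals), yc = yc,
                 nRemoved = flt$nRemoved, removalRule = flt$removalRule),
            class = "correctedPhenotype")
}

#' @export
print.correctedPhenotype <- function(x, ...) {
  cat("correctedPhenotype:", length(x$yc), "records,", x$nRemoved,
      "removed (", x$removalRule, ")\n")
  invisible(x)
}

#' Write corrected phenotypes as a two-column id/value file
#'
#' @param cp a \code{correctedPhenotype}.
#' @param file output path (tab-separated).
#' @return invisibly, NULL.
#' @export
writeCorrected <- function(cp, file) {
  write.table(data.frame(id = cp$sampleIds, yc = cp$yc), file,
              quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(NULL)
}
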