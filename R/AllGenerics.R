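#' @rdname GenotypeData-class
#' @param x a \code{GenotypeData} or \code{GRMatrix} object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpMeta", function(x) standardGeneric("snpMeta"))

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GRMatrix-class
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))

#' @rdname GRMatrix-class
#' @export
setGeneric("grmWeights", function(x) standardGeneric("grmWeights"))
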