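#' @rdname GenotypeData-class
#' @param x a \linkS4class{GenotypeData} object.
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeData-class
#' @param value replacement DataFrame.
#' @export
setGeneric("sampleInfo<-", function(x, value) standardGeneric("sampleInfo<-"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname JointTable-class
#' @param x a \linkS4class{JointTable}.
#' @export
setGeneric("jointCounts", function(x) standardGeneric("jointCounts"))

#' @rdname EffectTable-class
#' @param x an \linkS4class{EffectTable}.
#' @export
setGeneric("cellLogOR", function(x) standardGeneric("cellLogOR"))

#' @rdname EffectTable-class
#' @export
setGeneric("highRiskCells", function(x) standardGeneric("highRiskCells"))
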