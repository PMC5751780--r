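#' @rdname DCoxDataSet
#' @param x,object a package object
#' @export
setGeneric("factorNames", function(x) standardGeneric("factorNames"))

#' @rdname DCoxDataSet
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname DCoxDataSet
#' @export
setGeneric("factorTable", function(x) standardGeneric("factorTable"))

#' @rdname PairDesign-accessors
#' @param x a \linkS4class{PairDesign}
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname PairDesign-accessors
#' @export
setGeneric("pairIndices", function(x) standardGeneric("pairIndices"))

#' @rdname PairDesign-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname DCXGeneSet-accessors
#' @param x a \linkS4class{DCXGeneSet} or \linkS4class{DCoxFit}
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname DCXGeneSet-accessors
#' @export
setGeneric("dcxProfile", function(x) standardGeneric("dcxProfile"))

#' @rdname DCXGeneSet-accessors
#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))

#' @rdname DCoxResults-accessors
#' @param x a \linkS4class{DCoxResults}
#' @export
setGeneric("dcxSets", function(x) standardGeneric("dcxSets"))

#' @rdname DCoxResults-accessors
#' @export
setGeneric("candidateSets", function(x) standardGeneric("candidateSets"))

#' @rdname DCoxResults-accessors
#' @export
setGeneric("gatingTable", function(x) standardGeneric("gatingTable"))

#' @rdname DCoxResults-accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
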