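#' @rdname GroundTruthModel-class
#' @param object,x an object.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname GroundTruthModel-class
#' @export
setGeneric("precisionMatrices", function(x) standardGeneric("precisionMatrices"))

#' @rdname GroundTruthModel-class
#' @export
setGeneric("nodeScale", function(x) standardGeneric("nodeScale"))

#' True partial-correlation edge vector of one design cell
#'
#' @param x a [GroundTruthModel-class].
#' @param group,condition design cell.
#' @return numeric edge vector in row-major upper-triangle order.
#' @export
setGeneric("trueEdgeVector",
           function(x, group, condition) standardGeneric("trueEdgeVector"))

#' @rdname CohortTimeSeries-class
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname CohortTimeSeries-class
#' @param id,condition run key.
#' @export
setGeneric("seriesMatrix",
           function(x, id, condition) standardGeneric("seriesMatrix"))

#' @rdname ConnectivityEdges-class
#' @export
setGeneric("edgeVector", function(x) standardGeneric("edgeVector"))

#' @rdname ConnectivityEdges-class
#' @export
setGeneric("partialMatrix", function(x) standardGeneric("partialMatrix"))

#' @rdname PrecisionEstimate-class
#' @export
setGeneric("precisionMatrix", function(x) standardGeneric("precisionMatrix"))

#' @rdname EdgeExperiment-class
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname ClassificationReport-class
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname ClassificationReport-class
#' @export
setGeneric("perClassAccuracy", function(x) standardGeneric("perClassAccuracy"))

#' @rdname ClassificationReport-class
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname ClassificationReport-class
#' @export
setGeneric("permutationP", function(x) standardGeneric("permutationP"))
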