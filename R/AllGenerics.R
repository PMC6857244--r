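#' @include utils.R
NULL

#' Number of ordered objects
#'
#' Number of ordered objects (loci, SNPs, bins) represented by an object.
#'
#' @param x an object.
#' @return Integer count of objects.
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' Bandwidth of a banded object
#'
#' The bandwidth parameter \code{h}: pairs of objects separated by \code{h}
#' or more positions are treated as having similarity 0.
#'
#' @param x an object.
#' @return Integer bandwidth.
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))

#' @rdname bandValues
#' @export
setGeneric("bandValues", function(x) standardGeneric("bandValues"))

#' @rdname objectLabels
#' @export
setGeneric("objectLabels", function(x) standardGeneric("objectLabels"))

#' @rdname objectPositions
#' @export
setGeneric("objectPositions", function(x) standardGeneric("objectPositions"))

#' @rdname shiftDiagonal
#' @export
setGeneric("shiftDiagonal", function(x, lambda) standardGeneric("shiftDiagonal"))

#' @rdname merges
#' @export
setGeneric("merges", function(x) standardGeneric("merges"))

#' @rdname mergeHeights
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))

#' @rdname isMonotone
#' @export
setGeneric("isMonotone", function(x) standardGeneric("isMonotone"))

#' @rdname cutClusters
#' @export
setGeneric("cutClusters", function(x, K) standardGeneric("cutClusters"))

#' @rdname selectedK
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname clusterLabels
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname selectionTrace
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))
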