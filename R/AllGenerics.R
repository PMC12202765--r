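#' @rdname MidpointSet-class
#' @param x an object.
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname MidpointSet-class
#' @export
setGeneric("midpoints", function(x) standardGeneric("midpoints"))

#' @rdname SiteSet-class
#' @param x an object.
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @rdname SiteSet-class
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname PiledVector-class
#' @param x an object.
#' @export
setGeneric("pileCounts", function(x) standardGeneric("pileCounts"))

#' @rdname PiledVector-class
#' @export
setGeneric("hitProportion", function(x) standardGeneric("hitProportion"))

#' @rdname NucMapExperiment-class
#' @param x an object.
#' @export
setGeneric("sdMatrix", function(x) standardGeneric("sdMatrix"))

#' @rdname NucMapExperiment-class
#' @export
setGeneric("exceptionMask", function(x) standardGeneric("exceptionMask"))

#' @rdname ClusterResult-class
#' @param x an object.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @name accessors
#' @title Accessor methods
#' @description Slot accessors for the package's S4 classes.
#' @param x an object.
#' @keywords internal
NULL

#' @rdname MidpointSet-class
#' @exportMethod cellId
setMethod("cellId", "MidpointSet", function(x) x@cellId)

#' @rdname MidpointSet-class
#' @exportMethod midpoints
setMethod("midpoints", "MidpointSet", function(x) x@midpoints)

#' @rdname SiteSet-class
#' @exportMethod motifId
setMethod("motifId", "SiteSet", function(x) x@motifId)

#' @rdname SiteSet-class
#' @exportMethod siteTable
setMethod("siteTable", "SiteSet", function(x) x@sites)

#' @rdname PiledVector-class
#' @exportMethod pileCounts
setMethod("pileCounts", "PiledVector", function(x) x@counts)

#' @rdname PiledVector-class
#' @exportMethod hitProportion
setMethod("hitProportion", "PiledVector",
    function(x) sum(x@counts > 0L) / length(x@counts))

#' @rdname NucMapExperiment-class
#' @exportMethod sdMatrix
setMethod("sdMatrix", "NucMapExperiment",
    function(x) SummarizedExperiment::assay(x, "sd"))

#' @rdname NucMapExperiment-class
#' @exportMethod exceptionMask
setMethod("exceptionMask", "NucMapExperiment",
    function(x) SummarizedExperiment::assay(x, "exception"))

#' @rdname ClusterResult-class
#' @exportMethod clusterLabels
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname MidpointSet-class
#' @param object a \linkS4class{MidpointSet}.
#' @exportMethod show
setMethod("show", "MidpointSet", function(object) {
    n <- sum(lengths(object@midpoints))
    cat(sprintf(
        "MidpointSet '%s' (%s): %d midpoints on %d chromosome(s), %d/%d fragments dropped by length filter\n",
        object@cellId, object@mode, n, length(object@midpoints),
        object@nDropped, object@nInput))
})

#' @rdname SiteSet-class
#' @param object a \linkS4class{SiteSet}.
#' @exportMethod show
setMethod("show", "SiteSet", function(object) {
    cat(sprintf("SiteSet '%s' (%s): %d site(s)\n",
        object@motifId, object@provenance, nrow(object@sites)))
})

#' @rdname PiledVector-class
#' @param object a \linkS4class{PiledVector}.
#' @exportMethod show
setMethod("show", "PiledVector", function(object) {
    cat(sprintf(
        "PiledVector: %d bins (window %d bp, bin %d bp), %d sites, %d midpoints, hit proportion %.3f\n",
        length(object@counts), object@window, object@bin, object@nSites,
        sum(object@counts), hitProportion(object)))
})

#' @rdname ClusterResult-class
#' @param object a \linkS4class{ClusterResult}.
#' @exportMethod show
setMethod("show", "ClusterResult", function(object) {
    k <- if (length(object@labels)) max(object@labels) else 0L
    cat(sprintf("ClusterResult (%s): %d cells in %d cluster(s)\n",
        object@method, length(object@labels), k))
})
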