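#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<-
NULL

#' MidpointSet: nucleosome dyad evidence for one cell
#'
#' Holds the fragment midpoints of a single cell after the fragment-length
#' filter, sorted per chromosome. Midpoints of 140-180 bp MNase fragments
#' (or 147-294 bp mononucleosomal scATAC fragments in \code{"atac"} mode)
#' approximate nucleosome dyad positions.
#'
#' @slot cellId character(1), opaque cell identifier.
#' @slot mode \code{"mnase"} or \code{"atac"}; the length filter that
#'   produced the midpoints.
#' @slot midpoints named list, one sorted integer vector of midpoint
#'   positions (bp) per chromosome.
#' @slot nDropped integer(1), fragments removed by the length filter.
#' @slot nInput integer(1), fragments before filtering.
#'
#' @exportClass MidpointSet
setClass("MidpointSet",
    representation(
        cellId    = "character",
        mode      = "character",
        midpoints = "list",
        nDropped  = "integer",
        nInput    = "integer"
    )
)

setValidity("MidpointSet", function(object) {
    msg <- character()
    if (length(object@cellId) != 1L || is.na(object@cellId) ||
        !nzchar(object@cellId))
        msg <- c(msg, "'cellId' must be a non-empty string")
    if (!object@mode %in% c("mnase", "atac"))
        msg <- c(msg, "'mode' must be 'mnase' or 'atac'")
    mp <- object@midpoints
    if (length(mp) && (is.null(names(mp)) || any(!nzchar(names(mp)))))
        msg <- c(msg, "'midpoints' must be named by chromosome")
    for (chr in names(mp)) {
        v <- mp[[chr]]
        if (!is.numeric(v))
            msg <- c(msg, sprintf("midpoints[['%s']] is not numeric", chr))
        else if (is.unsorted(v))
            msg <- c(msg, sprintf("midpoints[['%s']] is not sorted", chr))
    }
    if (length(msg)) msg else TRUE
})

#' SiteSet: candidate TFBS centers for one motif
#'
#' Candidate binding-site centers for a single motif, either scanned from a
#' genome or imported from a precomputed hit BED, optionally restricted to
#' accessible chromatin.
#'
#' @slot motifId character(1) motif identifier.
#' @slot sites data.frame with columns \code{chrom} (character),
#'   \code{center} (integer bp) and \code{strand} (\code{"+"} or \code{"-"}),
#'   sorted by (chrom, center) and unique on (chrom, center, strand).
#' @slot provenance \code{"scanned"}, \code{"imported"} or
#'   \code{"synthetic"}.
#'
#' @exportClass SiteSet
setClass("SiteSet",
    representation(
        motifId    = "character",
        sites      = "data.frame",
        provenance = "character"
    )
)

setValidity("SiteSet", function(object) {
    msg <- character()
    if (length(object@motifId) != 1L || !nzchar(object@motifId))
        msg <- c(msg, "'motifId' must be a non-empty string")
    if (!object@provenance %in% c("scanned", "imported", "synthetic"))
        msg <- c(msg, "'provenance' must be scanned/imported/synthetic")
    s <- object@sites
    need <- c("chrom", "center", "strand")
    if (!all(need %in% names(s))) {
        msg <- c(msg, "'sites' needs columns chrom, center, strand")
    } else if (nrow(s)) {
        if (!all(s$strand %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
        o <- order(s$chrom, s$center)
        if (!identical(o, seq_len(nrow(s))))
            msg <- c(msg, "'sites' must be sorted by (chrom, center)")
        if (anyDuplicated(s[, need]))
            msg <- c(msg, "duplicate (chrom, center, strand) rows")
    }
    if (length(msg)) msg else TRUE
})

#' MotifPFM: a position frequency matrix
#'
#' @slot id character(1) motif identifier (e.g. a JASPAR accession).
#' @slot name character(1) TF name.
#' @slot counts 4 x L non-negative matrix with rows A, C, G, T.
#'
#' @exportClass MotifPFM
setClass("MotifPFM",
    representation(id = "character", name = "character", counts = "matrix")
)

setValidity("MotifPFM", function(object) {
    msg <- character()
    cm <- object@counts
    if (!identical(rownames(cm), c("A", "C", "G", "T")))
        msg <- c(msg, "'counts' rows must be A, C, G, T")
    if (ncol(cm) < 4L)
        msg <- c(msg, "motif length must be >= 4")
    if (any(cm < 0) || any(!is.finite(cm)))
        msg <- c(msg, "'counts' must be finite and non-negative")
    if (ncol(cm) >= 1L && any(colSums(cm) <= 0))
        msg <- c(msg, "every column needs at least one positive count")
    if (length(msg)) msg else TRUE
})

#' PiledVector: piled-up midpoint counts around aligned site centers
#'
#' Binned fragment-midpoint counts over a +/- window around the aligned
#' centers of a SiteSet, summed across sites, for one (cell, motif) pair.
#' Index 1 corresponds to -window bp, the center bin to offset 0.
#'
#' @slot counts integer vector of length \code{2 * window / bin + 1}.
#' @slot window integer(1) half-width in bp (default pipeline value 400).
#' @slot bin integer(1) bin size in bp (default 1).
#' @slot nSites integer(1) number of site centers pooled.
#'
#' @exportClass PiledVector
setClass("PiledVector",
    representation(
        counts = "integer", window = "integer",
        bin = "integer", nSites = "integer"
    )
)

setValidity("PiledVector", function(object) {
    msg <- character()
    if (object@bin < 1L || object@window < 1L)
        msg <- c(msg, "'window' and 'bin' must be positive")
    if (object@window %% object@bin != 0L)
        msg <- c(msg, "'window' must be divisible by 'bin'")
    else if (length(object@counts) != 2L * (object@window %/% object@bin) + 1L)
        msg <- c(msg, "'counts' length must be 2*window/bin + 1")
    if (any(object@counts < 0L))
        msg <- c(msg, "'counts' must be non-negative")
    if (length(msg)) msg else TRUE
})

#' NucMapExperiment: summit-distance values for motifs x cells
#'
#' A \linkS4class{SummarizedExperiment} with motifs as rows (features) and
#' cells as columns (samples) and two assays: \code{"sd"}, the per
#' (motif, cell) summit distance, and \code{"exception"}, the logical QC
#' mask marking low-coverage piled-up vectors whose summit distance was
#' recorded as 0. Text serialisation (\code{\link{writeMatrixTSV}}) uses
#' the cells-x-motifs orientation.
#'
#' @exportClass NucMapExperiment
setClass("NucMapExperiment",
    contains = "SummarizedExperiment"
)

setValidity("NucMapExperiment", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("sd", "exception") %in% an)) {
        msg <- c(msg, "assays 'sd' and 'exception' are required")
    } else {
        sd <- SummarizedExperiment::assay(object, "sd")
        ex <- SummarizedExperiment::assay(object, "exception")
        if (!is.logical(ex))
            msg <- c(msg, "'exception' assay must be logical")
        if (any(sd < 0))
            msg <- c(msg, "summit distances must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' ClusterResult: cell cluster assignment
#'
#' @slot labels integer cluster ids (contiguous from 1) named by cell id.
#' @slot method \code{"tree"} or \code{"graph"}.
#' @slot params list of clustering parameters (k or resolution, linkage,
#'   k_nn, seed ...).
#'
#' @exportClass ClusterResult
setClass("ClusterResult",
    representation(labels = "integer", method = "character", params = "list")
)

setValidity("ClusterResult", function(object) {
    msg <- character()
    if (!object@method %in% c("tree", "graph"))
        msg <- c(msg, "'method' must be 'tree' or 'graph'")
    lab <- object@labels
    if (is.null(names(lab)) || any(!nzchar(names(lab))))
        msg <- c(msg, "'labels' must be named by cell id")
    if (length(lab) && !setequal(unique(lab), seq_len(max(lab))))
        msg <- c(msg, "cluster ids must be contiguous from 1")
    if (length(msg)) msg else TRUE
})
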