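#' Compute valley geometries for all (cell, motif) pairs
#'
#' The core matrix-stage loop: piles up each cell's midpoints around each
#' motif's site centers and extracts the valley geometry (dynamic center,
#' summits, summit distance, exception tag).
#'
#' @param mpsList named list of \linkS4class{MidpointSet}.
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param window,bin pile-up parameters (defaults 400 bp, 1 bp).
#' @param r,search,minHitProportion,sdMethod geometry parameters, see
#'   \code{\link{valleyGeometry}}.
#' @return data.frame with one row per (cell, motif): \code{cell},
#'   \code{motif}, \code{dc}, \code{uS}, \code{dS}, \code{sd},
#'   \code{hit_proportion}, \code{exception}.
#' @export
landscapeTable <- function(mpsList, siteSets, window = 400L, bin = 1L,
                           r = 20L, search = 200L,
                           minHitProportion = 0.05,
                           sdMethod = c("split", "pooled")) {
    sdMethod <- match.arg(sdMethod)
    kernel <- weightKernel()
    rows <- vector("list", length(mpsList) * length(siteSets))
    k <- 0L
    for (mps in mpsList) {
        for (ss in siteSets) {
            v <- pileUp(mps, ss, window = window, bin = bin)
            g <- valleyGeometry(v, r = r, search = search,
                                minHitProportion = minHitProportion,
                                sdMethod = sdMethod, kernel = kernel)
            k <- k + 1L
            rows[[k]] <- cbind(data.frame(cell = cellId(mps),
                                          motif = motifId(ss)), g)
        }
    }
    do.call(rbind, rows)
}

#' Run the matrix stage end to end
#'
#' Fragments -> midpoints -> per-pair valley geometry -> assembled
#' summit-distance matrix, optionally written to disk with a QC report.
#'
#' @param fragments fragment table (see \code{\link{loadFragments}}).
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param regions optional accessible regions used to filter sites
#'   (\code{extend} = 200 bp around region centers).
#' @param mode fragment-length mode, \code{"mnase"} or \code{"atac"}.
#' @param outDir optional output directory for \code{matrix.tsv},
#'   \code{exceptions.tsv}, \code{geometry.tsv} and \code{qc.tsv}.
#' @param ... passed to \code{\link{landscapeTable}}.
#' @return list with \code{nme} (\linkS4class{NucMapExperiment}),
#'   \code{geometry}, \code{midpoints} and \code{qc}.
#' @export
matrixStage <- function(fragments, siteSets, regions = NULL,
                        mode = c("mnase", "atac"), outDir = NULL, ...) {
    mode <- match.arg(mode)
    if (!is.null(regions))
        siteSets <- filterByAccessibility(siteSets, regions)
    mpsList <- toMidpoints(fragments, mode = mode)
    geom <- landscapeTable(mpsList, siteSets, ...)
    nme <- assembleMatrix(geom)
    qc <- data.frame(
        n_cells = length(mpsList),
        n_motifs = length(siteSets),
        n_fragments = nrow(fragments),
        n_dropped_length = sum(vapply(mpsList, function(m) m@nDropped,
                                      integer(1))),
        exception_rate = mean(geom$exception))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeMatrixTSV(nme, file.path(outDir, "matrix.tsv"),
                       file.path(outDir, "exceptions.tsv"))
        data.table::fwrite(geom, file.path(outDir, "geometry.tsv"),
                           sep = "\t", quote = FALSE)
        data.table::fwrite(qc, file.path(outDir, "qc.tsv"), sep = "\t",
                           quote = FALSE)
    }
    list(nme = nme, geometry = geom, midpoints = mpsList, qc = qc)
}

#' Run the clustering stage
#'
#' QC filtering, winsorisation, CV selection and clustering of an
#' assembled matrix.
#'
#' @param nme a \linkS4class{NucMapExperiment}.
#' @param method,k,resolution,kNN,seed see \code{\link{clusterCells}}.
#' @param maxCellException,maxMotifException,lower,upper,minCV filtering
#'   parameters.
#' @param outDir optional directory for \code{clusters.tsv} and
#'   \code{filtered_matrix.tsv}.
#' @return list with \code{clusters} (\linkS4class{ClusterResult}) and
#'   \code{filtered} (\linkS4class{NucMapExperiment}).
#' @export
clusterStage <- function(nme, method = "tree", k = 2L, resolution = 1,
                         kNN = 15L, seed = 0L,
                         maxCellException = 0.70,
                         maxMotifException = 0.90, lower = 1, upper = 99,
                         minCV = 0.5, outDir = NULL) {
    f <- filterMatrix(nme, maxCellException, maxMotifException)
    f <- winsorizeMotifs(f, lower, upper)
    f <- cvSelect(f, minCV)
    cr <- clusterCells(f, method = method, k = k,
                       resolution = resolution, kNN = kNN, seed = seed)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeClusterTSV(cr, file.path(outDir, "clusters.tsv"))
        writeMatrixTSV(f, file.path(outDir, "filtered_matrix.tsv"))
    }
    list(clusters = cr, filtered = f)
}

#' Run the TF-activity stage
#'
#' Per-cell (or pooled per-cluster) motif activity calls plus
#' cluster-specific hypergeometric enrichment.
#'
#' @param mpsList named list of per-cell \linkS4class{MidpointSet}.
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param regions accessible regions defining the default background.
#' @param labels named cluster labels (required for pooled mode and
#'   enrichment).
#' @param pooled run in pooled mode (default FALSE).
#' @param nsMin,pMax joint-filter thresholds.
#' @param background optional background \linkS4class{SiteSet} overriding
#'   the region-center default.
#' @param seed seed for background downsampling.
#' @param outDir optional directory for \code{calls.tsv} and
#'   \code{enrichment.tsv}.
#' @return list with \code{calls} and (per-cell mode with labels)
#'   \code{enrichment}.
#' @export
tfStage <- function(mpsList, siteSets, regions, labels = NULL,
                    pooled = FALSE, nsMin = 0.1, pMax = 0.01,
                    background = NULL, seed = 0L, outDir = NULL) {
    if (is.null(background))
        background <- backgroundFromRegions(regions, seed = seed)
    if (pooled) {
        if (is.null(labels)) stop("pooled mode needs cluster labels")
        calls <- pooledCalls(mpsList, labels, siteSets, background,
                             nsMin = nsMin, pMax = pMax)
        enr <- NULL
    } else {
        calls <- motifCalls(mpsList, siteSets, background, nsMin = nsMin,
                            pMax = pMax)
        enr <- if (is.null(labels)) NULL else
            clusterEnrichment(calls, labels)
    }
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeCallsTSV(calls, file.path(outDir, "calls.tsv"))
        if (!is.null(enr))
            writeCallsTSV(enr, file.path(outDir, "enrichment.tsv"))
    }
    list(calls = calls, enrichment = enr)
}
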