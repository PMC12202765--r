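#' Assemble the cell-motif summit-distance matrix
#'
#' Builds a \linkS4class{NucMapExperiment} (motifs x cells) from per
#' (cell, motif) valley geometries. Exception-tagged entries carry a summit
#' distance of 0 and \code{TRUE} in the \code{"exception"} assay.
#'
#' @param geometry data.frame with columns \code{cell}, \code{motif},
#'   \code{sd}, \code{exception} (one row per pair, every pair present
#'   exactly once).
#' @return a \linkS4class{NucMapExperiment}.
#' @export
assembleMatrix <- function(geometry) {
    stopifnot(all(c("cell", "motif", "sd", "exception") %in%
                  names(geometry)))
    cells <- unique(geometry$cell)
    motifs <- unique(geometry$motif)
    key <- paste(geometry$cell, geometry$motif, sep = "\r")
    dup <- key[duplicated(key)]
    if (length(dup)) {
        pr <- strsplit(dup[1L], "\r")[[1L]]
        stop("duplicate (cell, motif) pair: (", pr[1L], ", ", pr[2L], ")")
    }
    full <- expand.grid(motif = motifs, cell = cells,
                        stringsAsFactors = FALSE)
    fullKey <- paste(full$cell, full$motif, sep = "\r")
    miss <- setdiff(fullKey, key)
    if (length(miss)) {
        pr <- strsplit(miss[1L], "\r")[[1L]]
        stop("missing (cell, motif) pair: (", pr[1L], ", ", pr[2L], ")")
    }
    if (any(geometry$sd[geometry$exception] != 0))
        stop("exception-tagged entries must have sd = 0")
    idx <- match(fullKey, key)
    sd <- matrix(geometry$sd[idx], nrow = length(motifs),
                 dimnames = list(motifs, cells))
    ex <- matrix(geometry$exception[idx], nrow = length(motifs),
                 dimnames = list(motifs, cells))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(sd = sd, exception = ex))
    new("NucMapExperiment", se)
}

#' Exception-based QC filtering of cells and motifs
#'
#' Drops cells whose proportion of exception tags exceeds
#' \code{maxCellException}, then motifs whose exception proportion over the
#' retained cells exceeds \code{maxMotifException}. Both comparisons are
#' strict (a cell at exactly the cutoff is retained). The two passes always
#' run in this order.
#'
#' @param nme a \linkS4class{NucMapExperiment}.
#' @param maxCellException cell cutoff (default 0.70).
#' @param maxMotifException motif cutoff (default 0.90).
#' @return filtered \linkS4class{NucMapExperiment}.
#' @export
filterMatrix <- function(nme, maxCellException = 0.70,
                         maxMotifException = 0.90) {
    ex <- exceptionMask(nme)
    keepCells <- colMeans(ex) <= maxCellException
    if (!any(keepCells))
        stop("all cells exceed the exception cutoff (",
             maxCellException, "); consider raising 'maxCellException' ",
             "or checking coverage")
    nme <- nme[, keepCells]
    ex <- exceptionMask(nme)
    keepMotifs <- rowMeans(ex) <= maxMotifException
    if (!any(keepMotifs))
        stop("all motifs exceed the exception cutoff (",
             maxMotifException, ")")
    nme[keepMotifs, ]
}

#' Winsorize summit distances within each motif
#'
#' Values below the lower or above the upper percentile of their motif are
#' replaced by the percentile value (type-7 quantiles). Exception zeros
#' participate as ordinary values.
#'
#' @param nme a \linkS4class{NucMapExperiment}.
#' @param lower,upper percentile limits in [0, 100] (defaults 1 and 99).
#' @return winsorized \linkS4class{NucMapExperiment}.
#' @export
winsorizeMotifs <- function(nme, lower = 1, upper = 99) {
    stopifnot(lower >= 0, upper <= 100, lower < upper)
    sd <- sdMatrix(nme)
    for (i in seq_len(nrow(sd))) {
        q <- stats::quantile(sd[i, ], c(lower, upper) / 100, names = FALSE,
                             type = 7)
        sd[i, ] <- pmin(pmax(sd[i, ], q[1L]), q[2L])
    }
    SummarizedExperiment::assay(nme, "sd") <- sd
    nme
}

#' Select high-variability motifs by coefficient of variation
#'
#' Per motif, CV = sample standard deviation / mean of the summit-distance
#' values across cells (0 when the mean is 0). Motifs with CV strictly
#' above \code{minCV} are retained.
#'
#' @param nme a \linkS4class{NucMapExperiment}.
#' @param minCV threshold (default 0.5).
#' @return \linkS4class{NucMapExperiment} restricted to variable motifs,
#'   with the per-motif CV stored in \code{rowData(.)$cv}.
#' @export
cvSelect <- function(nme, minCV = 0.5) {
    sd <- sdMatrix(nme)
    if (ncol(sd) < 2L) stop("CV selection needs at least 2 cells")
    mu <- rowMeans(sd)
    sdev <- apply(sd, 1L, stats::sd)
    cv <- ifelse(mu == 0, 0, sdev / mu)
    SummarizedExperiment::rowData(nme)$cv <- cv
    nme[cv > minCV, ]
}

## cells x motifs matrix with per-motif z-scoring; zero-variance motifs
## contribute a constant 0 column
.standardizedCells <- function(nme) {
    x <- t(sdMatrix(nme))
    x <- scale(x)
    x[!is.finite(x)] <- 0
    x
}

#' Cluster cells on the filtered summit-distance matrix
#'
#' \code{"tree"}: per-motif z-scoring, Euclidean distance, Ward linkage
#' (\code{ward.D2}), cut to \code{k} clusters. \code{"graph"}: k-nearest-
#' neighbour graph on cosine distances of the z-scored matrix, Louvain
#' community detection at the given resolution.
#'
#' @param nme a filtered, CV-selected \linkS4class{NucMapExperiment}.
#' @param method \code{"tree"} or \code{"graph"}.
#' @param k number of clusters (tree method).
#' @param resolution Louvain resolution (graph method, default 1).
#' @param kNN neighbours for the graph method (default 15).
#' @param seed RNG seed for the graph method.
#' @return a \linkS4class{ClusterResult}.
#' @export
clusterCells <- function(nme, method = c("tree", "graph"), k = 2L,
                         resolution = 1, kNN = 15L, seed = 0L) {
    method <- match.arg(method)
    if (nrow(nme) == 0L) stop("no motifs left to cluster on")
    x <- .standardizedCells(nme)
    n <- nrow(x)
    if (method == "tree") {
        if (k < 1L || k > n)
            stop("'k' must be between 1 and the number of cells (", n, ")")
        hc <- stats::hclust(stats::dist(x), method = "ward.D2")
        lab <- stats::cutree(hc, k = k)
        params <- list(k = k, linkage = "ward.D2", distance = "euclidean")
    } else {
        if (n < 3L) stop("graph clustering needs at least 3 cells")
        kNN <- min(kNN, n - 1L)
        nrm <- sqrt(rowSums(x^2))
        nrm[nrm == 0] <- 1
        xs <- x / nrm
        sim <- tcrossprod(xs)
        edges <- integer(0)
        for (i in seq_len(n)) {
            nb <- setdiff(order(sim[i, ], decreasing = TRUE), i)[seq_len(kNN)]
            edges <- c(edges, rbind(i, nb))
        }
        g <- igraph::simplify(igraph::make_graph(edges, n = n,
                                                 directed = FALSE))
        set.seed(seed)
        cm <- igraph::cluster_louvain(g, resolution = resolution)
        lab <- igraph::membership(cm)
        params <- list(resolution = resolution, kNN = kNN, seed = seed)
    }
    ## contiguous cluster ids in order of first appearance
    lab <- as.integer(lab)
    lab <- stats::setNames(as.integer(factor(lab, levels = unique(lab))),
                           rownames(x))
    new("ClusterResult", labels = lab, method = method, params = params)
}

#' Two-dimensional embedding of cells
#'
#' Convenience visualisation only: UMAP (via the \pkg{uwot} package) on the
#' z-scored matrix when available and \code{n >= 5}, otherwise the first
#' two principal components, with a warning.
#'
#' @param nme a filtered \linkS4class{NucMapExperiment}.
#' @param seed RNG seed.
#' @return data.frame with \code{cell}, \code{dim1}, \code{dim2}.
#' @export
embedCells <- function(nme, seed = 0L) {
    x <- .standardizedCells(nme)
    useUmap <- nrow(x) >= 5L && requireNamespace("uwot", quietly = TRUE)
    if (useUmap) {
        set.seed(seed)
        co <- uwot::umap(x, n_neighbors = min(15L, nrow(x) - 1L))
    } else {
        warning("falling back to PCA coordinates")
        p <- stats::prcomp(x, center = FALSE)$x
        co <- cbind(p[, 1L], if (ncol(p) >= 2L) p[, 2L] else 0)
    }
    data.frame(cell = rownames(x), dim1 = co[, 1L], dim2 = co[, 2L],
               row.names = NULL)
}

#' Matrix and cluster-table text serialisation
#'
#' \code{writeMatrixTSV} writes the summit-distance matrix as cells x
#' motifs (first column \code{cell_id}, header = motif ids), plus an
#' optional parallel exception-mask file. \code{readMatrixTSV} reads the
#' pair back into a \linkS4class{NucMapExperiment}.
#'
#' @param nme a \linkS4class{NucMapExperiment}.
#' @param path matrix TSV path.
#' @param exceptionPath optional mask TSV path.
#' @return \code{path} invisibly / the reconstructed object.
#' @export
writeMatrixTSV <- function(nme, path, exceptionPath = NULL) {
    writeOne <- function(m, p) {
        df <- data.frame(cell_id = colnames(m), t(m), check.names = FALSE)
        data.table::fwrite(df, p, sep = "\t", quote = FALSE)
    }
    writeOne(sdMatrix(nme), path)
    if (!is.null(exceptionPath))
        writeOne(exceptionMask(nme) * 1L, exceptionPath)
    invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path, exceptionPath = NULL) {
    readOne <- function(p) {
        dt <- data.table::fread(p, header = TRUE, sep = "\t")
        m <- t(as.matrix(dt[, -1L]))
        colnames(m) <- dt[[1L]]
        m
    }
    sd <- readOne(path)
    ex <- if (is.null(exceptionPath)) {
        matrix(FALSE, nrow(sd), ncol(sd), dimnames = dimnames(sd))
    } else {
        readOne(exceptionPath) > 0
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(sd = sd, exception = ex))
    new("NucMapExperiment", se)
}

#' @rdname writeMatrixTSV
#' @param cr a \linkS4class{ClusterResult}.
#' @export
writeClusterTSV <- function(cr, path) {
    data.table::fwrite(
        data.frame(cell_id = names(clusterLabels(cr)),
                   cluster = as.integer(clusterLabels(cr))),
        path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readClusterTSV <- function(path) {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    if (!all(c("cell_id", "cluster") %in% names(dt)))
        stop("'", path, "': columns cell_id, cluster expected")
    stats::setNames(as.integer(dt$cluster), dt$cell_id)
}
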