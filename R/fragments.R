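#' Fragment-length bounds for the two supported assay modes
#'
#' Nucleosome-sized fragments: 140-180 bp for scMNase-seq, 147-294 bp for
#' mononucleosomal scATAC-seq fragments. Bounds are inclusive.
#'
#' @param mode \code{"mnase"} or \code{"atac"}.
#' @return integer(2), the closed length interval.
#' @export
fragmentLengthBounds <- function(mode = c("mnase", "atac")) {
    mode <- match.arg(mode)
    if (mode == "mnase") c(140L, 180L) else c(147L, 294L)
}

#' Load per-cell fragment records
#'
#' Reads BED-like fragment files into a single fragment table with
#' 0-based half-open coordinates. Two layouts are supported:
#' \code{"per_cell_bed"} (BED3; one file per cell, the filename stem is the
#' cell id) and \code{"multi_cell_fragments"} (single 4+ column file with a
#' cell barcode in column 4). Files may be gzip-compressed.
#'
#' @param paths character vector of file paths (length 1 for
#'   \code{multi_cell_fragments}).
#' @param format input layout.
#' @param cellIds optional character vector overriding the filename-stem
#'   cell ids for \code{per_cell_bed}.
#' @return a \code{data.table} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{cell}. Attribute \code{"nMalformed"} counts skipped
#'   comment/header lines.
#' @export
loadFragments <- function(paths,
                          format = c("per_cell_bed", "multi_cell_fragments"),
                          cellIds = NULL) {
    format <- match.arg(format)
    for (p in paths)
        if (!file.exists(p)) stop("fragment file not found: ", p)
    if (format == "multi_cell_fragments" && length(paths) != 1L)
        stop("multi_cell_fragments expects a single file")

    readOne <- function(path, cell) {
        ncol <- if (is.null(cell)) 4L else 3L
        dt <- tryCatch(
            suppressWarnings(data.table::fread(path, header = FALSE,
                select = seq_len(ncol), sep = "\t", fill = TRUE,
                blank.lines.skip = TRUE,
                colClasses = list(character = 1L))),
            error = function(e) stop("cannot parse '", path, "': ",
                conditionMessage(e), call. = FALSE))
        if (nrow(dt) == 0L) {
            warning("empty fragment file: ", path)
            return(data.table::data.table(chrom = character(),
                start = integer(), end = integer(), cell = character()))
        }
        if (ncol(dt) < ncol)
            stop("'", path, "': expected at least ", ncol, " columns")
        names(dt)[seq_len(ncol)] <-
            if (is.null(cell)) c("chrom", "start", "end", "cell")
            else c("chrom", "start", "end")
        start <- suppressWarnings(as.integer(dt[["start"]]))
        end <- suppressWarnings(as.integer(dt[["end"]]))
        bad <- which(is.na(start) | is.na(end))
        if (length(bad))
            stop("'", path, "': unparseable coordinates at line ", bad[1L])
        bad <- which(end <= start)
        if (length(bad))
            stop("'", path, "': end <= start at line ", bad[1L])
        dt$start <- start
        dt$end <- end
        if (!is.null(cell)) dt$cell <- cell
        dt[, c("chrom", "start", "end", "cell"), with = FALSE]
    }

    if (format == "per_cell_bed") {
        if (is.null(cellIds)) {
            cellIds <- sub("\\.(bed|txt|tsv)(\\.gz)?$", "", basename(paths))
        } else if (length(cellIds) != length(paths)) {
            stop("'cellIds' must match 'paths' in length")
        }
        out <- data.table::rbindlist(
            mapply(readOne, paths, cellIds, SIMPLIFY = FALSE))
    } else {
        out <- readOne(paths, NULL)
    }
    if (nrow(out) == 0L && length(paths))
        warning("no fragments loaded")
    out[]
}

#' Reduce fragments to nucleosome dyad midpoints per cell
#'
#' Applies the mode's inclusive fragment-length filter and converts each
#' retained fragment to a single midpoint, \code{floor((start + end) / 2)}.
#' Duplicate fragments are retained: each fragment contributes exactly one
#' midpoint.
#'
#' @param fragments fragment table as returned by \code{\link{loadFragments}}.
#' @param mode \code{"mnase"} (140-180 bp) or \code{"atac"} (147-294 bp).
#' @return named list of \linkS4class{MidpointSet}, one per cell (input
#'   order of first appearance).
#' @export
toMidpoints <- function(fragments, mode = c("mnase", "atac")) {
    mode <- match.arg(mode)
    bounds <- fragmentLengthBounds(mode)
    stopifnot(all(c("chrom", "start", "end", "cell") %in% names(fragments)))
    cells <- unique(fragments$cell)
    len <- fragments$end - fragments$start
    keep <- len >= bounds[1L] & len <= bounds[2L]
    mid <- (fragments$start + fragments$end) %/% 2L
    out <- lapply(cells, function(cl) {
        idx <- fragments$cell == cl
        m <- mid[idx & keep]
        chr <- fragments$chrom[idx & keep]
        bychr <- split(m, chr)
        bychr <- lapply(bychr, function(v) sort(as.integer(v)))
        new("MidpointSet", cellId = cl, mode = mode,
            midpoints = bychr,
            nDropped = as.integer(sum(idx & !keep)),
            nInput = as.integer(sum(idx)))
    })
    names(out) <- cells
    out
}

#' Write fragments back to BED
#'
#' @param fragments fragment table (\code{chrom}, \code{start}, \code{end},
#'   \code{cell}).
#' @param path output file.
#' @param format \code{"multi_cell_fragments"} writes 4 columns including
#'   the cell barcode; \code{"per_cell_bed"} writes BED3 (the table must
#'   then hold a single cell).
#' @return \code{path}, invisibly.
#' @export
writeFragments <- function(fragments, path,
                           format = c("multi_cell_fragments",
                                      "per_cell_bed")) {
    format <- match.arg(format)
    cols <- c("chrom", "start", "end", "cell")
    if (format == "per_cell_bed") {
        if (length(unique(fragments$cell)) > 1L)
            stop("per_cell_bed output requires a single cell")
        cols <- cols[1:3]
    }
    data.table::fwrite(fragments[, cols, with = FALSE], path, sep = "\t",
        col.names = FALSE, quote = FALSE)
    invisible(path)
}
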