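#' Parse motifs from a JASPAR-format PFM file
#'
#' Reads the JASPAR text format: a \code{">ID NAME"} header followed by four
#' base rows of the form \code{"A  [ 4 19 0 ... ]"}. Rows may appear in any
#' order; they are normalised to A, C, G, T.
#'
#' @param path JASPAR PFM text file.
#' @return named list of \linkS4class{MotifPFM} in file order.
#' @export
parseJaspar <- function(path) {
    if (!file.exists(path)) stop("PFM file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    heads <- grep("^>", lines)
    if (!length(heads)) stop("no JASPAR records in ", path)
    ends <- c(heads[-1L] - 1L, length(lines))
    out <- vector("list", length(heads))
    for (k in seq_along(heads)) {
        hd <- sub("^>\\s*", "", lines[heads[k]])
        toks <- strsplit(trimws(hd), "\\s+")[[1L]]
        id <- toks[1L]
        name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
        body <- lines[seq(heads[k] + 1L, ends[k])]
        rows <- list()
        for (ln in body) {
            m <- regmatches(ln, regexec("^\\s*([ACGTacgt])\\s*\\[?([^]]*)\\]?", ln))[[1L]]
            if (length(m) < 3L)
                stop("motif ", id, ": unparseable count row: ", ln)
            base <- toupper(m[2L])
            vals <- suppressWarnings(as.numeric(
                strsplit(trimws(m[3L]), "\\s+")[[1L]]))
            if (any(is.na(vals)))
                stop("motif ", id, ": non-numeric counts in ", base, " row")
            rows[[base]] <- vals
        }
        miss <- setdiff(c("A", "C", "G", "T"), names(rows))
        if (length(miss))
            stop("motif ", id, ": missing ", paste(miss, collapse = ","),
                 " row")
        L <- unique(lengths(rows))
        if (length(L) != 1L)
            stop("motif ", id, ": base rows have unequal lengths")
        counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
        out[[k]] <- new("MotifPFM", id = id, name = name, counts = counts)
    }
    names(out) <- vapply(out, function(p) p@id, character(1))
    out
}

## log2-odds score matrix with a MOODS-like pseudocount distributed by the
## background composition
pfmScoreMatrix <- function(pfm, bg, pseudocount = 0.8) {
    cm <- pfm@counts
    n <- colSums(cm)
    p <- sweep(cm + pseudocount * bg, 2L, n + pseudocount, "/")
    log2(p / bg)
}

#' Exact score threshold for a match p-value
#'
#' Computes, by dynamic programming over the discretised per-position score
#' distribution, the smallest score \code{t} such that a random background
#' sequence attains log-odds score \code{>= t} with probability at most
#' \code{pvalue}. This is the thresholding rule used by log-odds motif
#' scanners.
#'
#' @param scores 4 x L log-odds score matrix (rows A, C, G, T).
#' @param bg background base frequencies (A, C, G, T), summing to 1.
#' @param pvalue match p-value.
#' @param granularity discretisation unit for scores (default 1/1000).
#' @return list with \code{threshold} (on the original score scale) and
#'   \code{tailProb}, the achieved P(score >= threshold).
#' @export
pfmScoreThreshold <- function(scores, bg, pvalue = 1e-4,
                              granularity = 1e-3) {
    iscores <- round(scores / granularity)
    L <- ncol(iscores)
    ## convolve the per-position integer score distributions under bg
    cur <- c(1)
    curLo <- 0L
    for (j in seq_len(L)) {
        sj <- iscores[, j]
        newLo <- curLo + min(sj)
        newHi <- curLo + length(cur) - 1L + max(sj)
        nxt <- numeric(newHi - newLo + 1L)
        for (b in 1:4) {
            off <- sj[b] - newLo + curLo
            idx <- seq_along(cur) + off
            nxt[idx] <- nxt[idx] + cur * bg[b]
        }
        cur <- nxt
        curLo <- newLo
    }
    tail <- rev(cumsum(rev(cur)))
    ok <- which(tail <= pvalue)
    if (!length(ok)) {
        thr <- curLo + length(cur) # above max: nothing passes
        tp <- 0
    } else {
        thr <- curLo + ok[1L] - 1L
        tp <- tail[ok[1L]]
    }
    list(threshold = thr * granularity, tailProb = tp)
}

## integer base codes: A=1 C=2 G=3 T=4, anything else 0
.baseCodes <- function(seq) {
    v <- match(strsplit(toupper(as.character(seq)), "")[[1L]],
               c("A", "C", "G", "T"))
    v[is.na(v)] <- 0L
    v
}

## score all windows of a coded sequence against a 4 x L score matrix.
## N (code 0) positions take the column minimum so they can never favour
## a match.
.scanScores <- function(codes, scores) {
    L <- ncol(scores)
    nw <- length(codes) - L + 1L
    if (nw < 1L) return(numeric(0))
    sm <- rbind(apply(scores, 2L, min), scores) # row 1 = N
    acc <- numeric(nw)
    for (j in seq_len(L))
        acc <- acc + sm[codes[j:(j + nw - 1L)] + 1L, j]
    acc
}

#' Scan a genome for motif matches
#'
#' Scans both strands of a genome with a log-odds matrix derived from a PFM,
#' keeping windows whose score reaches the exact p-value threshold computed
#' by \code{\link{pfmScoreThreshold}}. The hit center is the floor midpoint
#' of the matched window, identical for both strands.
#'
#' @param pfm a \linkS4class{MotifPFM}.
#' @param genome a \code{Biostrings::DNAStringSet} or FASTA file path.
#' @param pvalue match p-value threshold (default 1e-4).
#' @param bg background base frequencies A, C, G, T; estimated from the
#'   genome when \code{NULL}.
#' @param pseudocount PFM pseudocount (default 0.8).
#' @return a \linkS4class{SiteSet} with provenance \code{"scanned"}.
#' @export
scanGenome <- function(pfm, genome, pvalue = 1e-4, bg = NULL,
                       pseudocount = 0.8) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    if (length(genome) == 0L)
        return(newSiteSet(pfm@id, data.frame(chrom = character(),
            center = integer(), strand = character()), "scanned"))
    if (is.null(bg)) {
        fr <- colSums(Biostrings::letterFrequency(genome,
            c("A", "C", "G", "T")))
        bg <- if (sum(fr) == 0) rep(0.25, 4) else fr / sum(fr)
    }
    bg <- pmax(bg, 1e-6)
    bg <- bg / sum(bg)
    scores <- pfmScoreMatrix(pfm, bg, pseudocount)
    thr <- pfmScoreThreshold(scores, bg, pvalue)$threshold
    L <- ncol(scores)
    ## reverse-complement score matrix scans the minus strand on the
    ## forward sequence
    rcScores <- scores[4:1, L:1, drop = FALSE]
    rownames(rcScores) <- c("A", "C", "G", "T")
    hits <- list()
    chromNames <- sub("\\s.*$", "", names(genome))
    for (i in seq_along(genome)) {
        codes <- .baseCodes(genome[[i]])
        if (length(codes) < L) next
        ## half-open integer comparison guard: keep scores within rounding
        ## noise of the threshold
        eps <- 1e-9
        fw <- which(.scanScores(codes, scores) >= thr - eps)
        rv <- which(.scanScores(codes, rcScores) >= thr - eps)
        mk <- function(starts, strand) {
            if (!length(starts)) return(NULL)
            data.frame(chrom = chromNames[i],
                center = as.integer((starts - 1L) + (L - 1L) %/% 2L),
                strand = strand)
        }
        hits[[length(hits) + 1L]] <- mk(fw, "+")
        hits[[length(hits) + 1L]] <- mk(rv, "-")
    }
    hits <- do.call(rbind, hits)
    if (is.null(hits))
        hits <- data.frame(chrom = character(), center = integer(),
                           strand = character())
    newSiteSet(pfm@id, hits, "scanned")
}

#' Construct a SiteSet
#'
#' Sorts sites by (chrom, center) and removes duplicate
#' (chrom, center, strand) triples.
#'
#' @param motifId motif identifier.
#' @param sites data.frame with \code{chrom}, \code{center}, \code{strand}.
#' @param provenance \code{"scanned"}, \code{"imported"} or
#'   \code{"synthetic"}.
#' @return a \linkS4class{SiteSet}.
#' @export
newSiteSet <- function(motifId, sites, provenance = "imported") {
    sites <- sites[!duplicated(sites[, c("chrom", "center", "strand")]), ,
                   drop = FALSE]
    sites <- sites[order(sites$chrom, sites$center), , drop = FALSE]
    rownames(sites) <- NULL
    sites$center <- as.integer(sites$center)
    new("SiteSet", motifId = motifId, sites = sites,
        provenance = provenance)
}

#' Restrict candidate sites to accessible chromatin
#'
#' Each accessible region is replaced by a fixed-width interval
#' \code{[center - extend, center + extend)} around its midpoint; intervals
#' are merged into a union and a site is retained iff its center lies
#' inside the union.
#'
#' @param sites a \linkS4class{SiteSet} or list of them.
#' @param regions data.frame of accessible regions (\code{chrom},
#'   \code{start}, \code{end}; 0-based half-open).
#' @param extend half-width of the recentred regions in bp (default 200).
#' @return filtered \linkS4class{SiteSet} (or list of them).
#' @export
filterByAccessibility <- function(sites, regions, extend = 200L) {
    if (is.list(sites))
        return(lapply(sites, filterByAccessibility, regions = regions,
                      extend = extend))
    centers <- (regions$start + regions$end) %/% 2L
    byChrom <- split(centers, regions$chrom)
    union <- lapply(byChrom, function(ct) {
        IRanges::reduce(IRanges::IRanges(start = ct - extend,
                                         end = ct + extend - 1L))
    })
    s <- sites@sites
    keep <- logical(nrow(s))
    for (chr in names(union)) {
        idx <- which(s$chrom == chr)
        if (!length(idx)) next
        q <- IRanges::IRanges(start = s$center[idx], width = 1L)
        keep[idx] <- IRanges::overlapsAny(q, union[[chr]])
    }
    newSiteSet(sites@motifId, s[keep, , drop = FALSE], sites@provenance)
}

#' Read precomputed motif hits from a BED6 file
#'
#' Column 4 (name) carries the motif id; the hit center is the floor
#' midpoint of the interval.
#'
#' @param path BED6 file.
#' @return named list of \linkS4class{SiteSet} (provenance
#'   \code{"imported"}).
#' @export
readSitesBED <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
        colClasses = list(character = 1L))
    if (ncol(dt) < 6L) stop("'", path, "': BED6 with 6 columns expected")
    names(dt)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    dt$center <- (dt$start + dt$end) %/% 2L
    lapply(split(dt, by = "name", keep.by = TRUE), function(d) {
        newSiteSet(d$name[1L],
            data.frame(chrom = d$chrom, center = d$center,
                       strand = d$strand),
            "imported")
    })
}

#' Write SiteSets as BED6
#'
#' Each site is written as a 1 bp interval at its center with the motif id
#' in the name column.
#'
#' @param siteSets a \linkS4class{SiteSet} or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSitesBED <- function(siteSets, path) {
    if (!is.list(siteSets)) siteSets <- list(siteSets)
    rows <- lapply(siteSets, function(ss) {
        s <- ss@sites
        if (!nrow(s)) return(NULL)
        data.frame(chrom = s$chrom, start = s$center,
                   end = s$center + 1L, name = ss@motifId, score = 0L,
                   strand = s$strand)
    })
    dt <- data.table::rbindlist(rows)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read a BED3 file of genomic regions
#'
#' @param path BED file (first three columns used).
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
readRegionsBED <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
        select = 1:3, colClasses = list(character = 1L))
    names(dt) <- c("chrom", "start", "end")
    as.data.frame(dt)
}
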