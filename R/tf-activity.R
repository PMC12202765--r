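#' Count midpoints in center and flank zones around site centers
#'
#' For every site center c, midpoints at distance <= \code{centerBp} are
#' center counts and those at distance in (\code{centerBp}, \code{flankBp}]
#' (both sides) are flank counts. A midpoint near several sites is counted
#' once per site.
#'
#' @param mps a \linkS4class{MidpointSet}.
#' @param sites a \linkS4class{SiteSet}.
#' @param centerBp center half-width in bp (default 100).
#' @param flankBp outer flank bound in bp (default 200).
#' @return list with \code{nCenter}, \code{nFlank} and \code{F}
#'   (\code{nCenter / (nCenter + nFlank)}; \code{NA} when both are 0).
#' @export
countCenterFlank <- function(mps, sites, centerBp = 100L, flankBp = 200L) {
    s <- sites@sites
    mp <- mps@midpoints
    nCenter <- 0L
    nOuter <- 0L
    for (chr in intersect(unique(s$chrom), names(mp))) {
        v <- mp[[chr]]
        ci <- s$center[s$chrom == chr]
        cnt <- function(half)
            sum(findInterval(ci + half, v) -
                findInterval(ci - half - 1L, v))
        nCenter <- nCenter + cnt(centerBp)
        nOuter <- nOuter + cnt(flankBp)
    }
    nFlank <- nOuter - nCenter
    FF <- if (nCenter + nFlank == 0L) NA_real_ else
        nCenter / (nCenter + nFlank)
    list(nCenter = as.integer(nCenter), nFlank = as.integer(nFlank),
         F = FF)
}

#' Nucleosome-free score
#'
#' \code{NS = log2(F_b / F_t)} where F is the center fraction
#' \code{n_center / (n_center + n_flank)} of the treatment (motif sites)
#' and background region sets. Positive NS means the treatment centers are
#' depleted of nucleosome fragments relative to background, i.e. more
#' accessible.
#'
#' @param treatment,background count lists from
#'   \code{\link{countCenterFlank}}.
#' @return list with \code{ns} (NA when not evaluable), \code{Ft},
#'   \code{Fb}, \code{evaluable}.
#' @export
nsScore <- function(treatment, background) {
    Ft <- treatment$F
    Fb <- background$F
    ok <- !is.na(Ft) && !is.na(Fb) && Ft > 0 && Fb > 0
    list(ns = if (ok) log2(Fb) - log2(Ft) else NA_real_,
         Ft = Ft, Fb = Fb, evaluable = ok)
}

#' Independence test on the center/flank x treatment/background table
#'
#' Builds the 2 x 2 contingency table (rows center/flank, columns
#' treatment/background) and tests whether the center-versus-flank split
#' depends on the source: Fisher's exact test (two-sided) when any
#' expected count is 5 or less, otherwise the chi-square test with Yates
#' continuity correction (configurable off). A zero row or column yields
#' p = 1 with a degenerate flag.
#'
#' @param treatment,background count lists from
#'   \code{\link{countCenterFlank}}.
#' @param correct apply the continuity correction in the chi-square branch
#'   (default TRUE).
#' @return list with \code{pvalue}, \code{test} (\code{"chisq"},
#'   \code{"fisher"} or \code{"none"}), \code{degenerate}.
#' @export
independenceTest <- function(treatment, background, correct = TRUE) {
    tab <- matrix(c(treatment$nCenter, treatment$nFlank,
                    background$nCenter, background$nFlank), nrow = 2L,
                  dimnames = list(c("center", "flank"),
                                  c("treatment", "background")))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
        return(list(pvalue = 1, test = "none", degenerate = TRUE))
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd <= 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
    } else {
        p <- stats::chisq.test(tab, correct = correct)$p.value
        test <- "chisq"
    }
    list(pvalue = min(1, p), test = test, degenerate = FALSE)
}

#' Build a background site set from accessible-region centers
#'
#' The default nucleosome-free-score background: the midpoints of the
#' accessible regions themselves, downsampled to at most \code{maxSites}
#' (seeded) when larger.
#'
#' @param regions accessible regions (\code{chrom}, \code{start},
#'   \code{end}).
#' @param maxSites downsampling cap (default 50000).
#' @param seed RNG seed for the downsampling.
#' @return a \linkS4class{SiteSet} with motif id \code{"background"}.
#' @export
backgroundFromRegions <- function(regions, maxSites = 50000L, seed = 0L) {
    centers <- (regions$start + regions$end) %/% 2L
    df <- data.frame(chrom = regions$chrom, center = centers,
                     strand = "+")
    if (nrow(df) > maxSites) {
        set.seed(seed)
        df <- df[sample.int(nrow(df), maxSites), , drop = FALSE]
    }
    newSiteSet("background", df, "imported")
}

#' Per-unit motif activity calls
#'
#' For every (cell, motif) pair, computes center/flank counts at the motif
#' sites and at the background sites, the nucleosome-free score and the
#' independence test, and applies the joint significance filter.
#'
#' @param mpsList named list of \linkS4class{MidpointSet} (one per cell or
#'   pooled unit).
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param background background \linkS4class{SiteSet} (e.g. from
#'   \code{\link{backgroundFromRegions}}).
#' @param nsMin,pMax joint-filter thresholds (defaults 0.1 and 0.01,
#'   strict inequalities).
#' @param correct continuity correction for the chi-square branch.
#' @return data.frame: \code{unit_id}, \code{motif_id}, \code{n_center},
#'   \code{n_flank}, \code{ns}, \code{pvalue}, \code{test},
#'   \code{evaluable}, \code{significant}.
#' @export
motifCalls <- function(mpsList, siteSets, background, nsMin = 0.1,
                       pMax = 0.01, correct = TRUE) {
    rows <- vector("list", length(mpsList) * length(siteSets))
    k <- 0L
    for (mps in mpsList) {
        bgc <- countCenterFlank(mps, background)
        for (ss in siteSets) {
            tc <- countCenterFlank(mps, ss)
            ns <- nsScore(tc, bgc)
            it <- independenceTest(tc, bgc, correct = correct)
            k <- k + 1L
            rows[[k]] <- data.frame(
                unit_id = cellId(mps), motif_id = motifId(ss),
                n_center = tc$nCenter, n_flank = tc$nFlank,
                ns = ns$ns, pvalue = it$pvalue, test = it$test,
                evaluable = ns$evaluable, significant = FALSE)
        }
    }
    calls <- do.call(rbind, rows)
    jointFilter(calls, nsMin = nsMin, pMax = pMax)
}

#' Joint significance filter
#'
#' A call is significant iff it is evaluable, \code{ns > nsMin} and
#' \code{pvalue < pMax} (both strict).
#'
#' @param calls data.frame of motif calls.
#' @param nsMin,pMax thresholds (defaults 0.1 and 0.01).
#' @return \code{calls} with the \code{significant} column set.
#' @export
jointFilter <- function(calls, nsMin = 0.1, pMax = 0.01) {
    calls$significant <- calls$evaluable &
        !is.na(calls$ns) & calls$ns > nsMin & calls$pvalue < pMax
    calls
}

#' Pool midpoints of several cells into one unit
#'
#' @param mpsList list of \linkS4class{MidpointSet} with a common mode.
#' @param label unit id of the pooled set.
#' @return a \linkS4class{MidpointSet}.
#' @export
poolMidpoints <- function(mpsList, label) {
    if (!length(mpsList)) stop("cannot pool an empty group")
    mode <- unique(vapply(mpsList, function(m) m@mode, character(1)))
    if (length(mode) != 1L) stop("mixed modes in pooled group")
    chroms <- unique(unlist(lapply(mpsList, function(m)
        names(m@midpoints))))
    mp <- lapply(chroms, function(chr)
        sort(unlist(lapply(mpsList, function(m) m@midpoints[[chr]]),
                    use.names = FALSE)))
    names(mp) <- chroms
    new("MidpointSet", cellId = label, mode = mode, midpoints = mp,
        nDropped = sum(vapply(mpsList, function(m) m@nDropped,
                              integer(1))),
        nInput = sum(vapply(mpsList, function(m) m@nInput, integer(1))))
}

#' Pooled-mode motif activity calls
#'
#' Concatenates the midpoints of all cells in each group (e.g. each
#' cluster) and runs the nucleosome-free score and independence test once
#' per (group, motif): the recommended route when single-cell coverage is
#' too sparse.
#'
#' @param mpsList named list of per-cell \linkS4class{MidpointSet}.
#' @param groups named vector mapping cell ids to group labels.
#' @param siteSets named list of \linkS4class{SiteSet}.
#' @param background background \linkS4class{SiteSet}.
#' @param ... passed to \code{\link{motifCalls}}.
#' @return data.frame of calls, one row per (group, motif).
#' @export
pooledCalls <- function(mpsList, groups, siteSets, background, ...) {
    if (!length(groups)) stop("empty grouping")
    miss <- setdiff(names(groups), names(mpsList))
    if (length(miss))
        stop("no midpoints for cell(s): ", paste(head(miss, 3L),
             collapse = ", "))
    pooled <- lapply(split(names(groups), as.character(groups)),
                     function(cells)
                         poolMidpoints(mpsList[cells], label = "pool"))
    pooled <- mapply(function(m, lb) { m@cellId <- lb; m },
                     pooled, names(pooled))
    motifCalls(pooled, siteSets, background, ...)
}

#' Cluster-specific motif enrichment
#'
#' Hypergeometric (upper-tail) test of whether significant cells for a
#' motif concentrate in a cluster: with N evaluable cells for the motif,
#' K of them significant, n_c evaluable cells in the cluster and k
#' significant in the cluster, \code{p = P(X >= k)} for
#' \code{X ~ Hypergeometric(N, K, n_c)}. P-values are BH-adjusted across
#' motifs within each cluster.
#'
#' @param calls per-cell motif calls (from \code{\link{motifCalls}}).
#' @param labels named vector mapping cell ids to cluster ids.
#' @return data.frame: \code{cluster}, \code{motif}, \code{k}, \code{n_c},
#'   \code{K}, \code{N}, \code{pvalue}, \code{p_adj}.
#' @export
clusterEnrichment <- function(calls, labels) {
    miss <- setdiff(unique(calls$unit_id), names(labels))
    if (length(miss))
        stop("cells without cluster label: ", paste(head(miss, 3L),
             collapse = ", "))
    calls$cluster <- labels[calls$unit_id]
    out <- list()
    for (cl in sort(unique(calls$cluster))) {
        for (mo in unique(calls$motif_id)) {
            cm <- calls[calls$motif_id == mo & calls$evaluable, ]
            N <- nrow(cm)
            K <- sum(cm$significant)
            inC <- cm$cluster == cl
            n_c <- sum(inC)
            k <- sum(cm$significant[inC])
            p <- if (K == 0L) 1 else
                stats::phyper(k - 1L, K, N - K, n_c, lower.tail = FALSE)
            out[[length(out) + 1L]] <- data.frame(
                cluster = cl, motif = mo, k = k, n_c = n_c, K = K, N = N,
                pvalue = p)
        }
    }
    res <- do.call(rbind, out)
    res$p_adj <- NA_real_
    for (cl in unique(res$cluster)) {
        idx <- res$cluster == cl
        res$p_adj[idx] <- stats::p.adjust(res$pvalue[idx], method = "BH")
    }
    res
}

#' Write motif-call and enrichment tables
#'
#' @param x a calls or enrichment data.frame.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeCallsTSV <- function(x, path) {
    data.table::fwrite(x, path, sep = "\t", quote = FALSE)
    invisible(path)
}
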