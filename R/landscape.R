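#' Pile up fragment midpoints around aligned site centers
#'
#' For every site center c, midpoints m with |m - c| <= window are placed at
#' bin index \code{floor((m - c + window) / bin) + 1}; per-site vectors are
#' summed across all sites of the motif. Strand is ignored (no flipping of
#' minus-strand sites).
#'
#' @param mps a \linkS4class{MidpointSet}.
#' @param sites a \linkS4class{SiteSet}.
#' @param window half-width in bp (default 400).
#' @param bin bin size in bp (default 1); must divide \code{window}.
#' @return a \linkS4class{PiledVector} of length \code{2*window/bin + 1}.
#' @export
pileUp <- function(mps, sites, window = 400L, bin = 1L) {
    window <- as.integer(window)
    bin <- as.integer(bin)
    if (window %% bin != 0L) stop("'window' must be divisible by 'bin'")
    nbins <- 2L * (window %/% bin) + 1L
    counts <- integer(nbins)
    s <- sites@sites
    mp <- mps@midpoints
    for (chr in intersect(unique(s$chrom), names(mp))) {
        v <- mp[[chr]]
        ci <- s$center[s$chrom == chr]
        lo <- findInterval(ci - window - 1L, v) + 1L
        hi <- findInterval(ci + window, v)
        n <- hi - lo + 1L
        pos <- n > 0L
        if (!any(pos)) next
        idx <- sequence(nvec = n[pos], from = lo[pos])
        offs <- v[idx] - rep(ci[pos], n[pos])
        binIdx <- (offs + window) %/% bin + 1L
        counts <- counts + tabulate(binIdx, nbins)
    }
    new("PiledVector", counts = as.integer(counts), window = window,
        bin = bin, nSites = nrow(s))
}

#' Gaussian distance-spreading weight kernel
#'
#' Symmetric weights \code{w_j = exp(-(j / scale)^2 / 2)} on offsets
#' \code{j = -halfSpan .. halfSpan}, used to smooth positioning scores into
#' the center-weighted score.
#'
#' @param halfSpan kernel half-span in bins (default 73).
#' @param scale Gaussian scale in bins (default 20).
#' @return numeric vector of length \code{2*halfSpan + 1}, names = offsets.
#' @export
weightKernel <- function(halfSpan = 73L, scale = 20) {
    j <- seq(-halfSpan, halfSpan)
    w <- exp(-(j / scale)^2 / 2)
    names(w) <- j
    w
}

#' Nucleosome positioning scores
#'
#' \code{S_i} is the fraction of midpoints in the 31-bin window centered on
#' bin i relative to the 201-bin window: a measure of local positional
#' consistency, in [0, 1]. Bins without full +/-outer support are
#' \code{NA}; bins whose 201-bin denominator is zero score 0.
#'
#' @param v a \linkS4class{PiledVector} or an integer count vector.
#' @param inner inner half-window in bins (default 15).
#' @param outer outer half-window in bins (default 100).
#' @return numeric vector of per-bin scores (NA where undefined).
#' @export
positioningScores <- function(v, inner = 15L, outer = 100L) {
    x <- if (is(v, "PiledVector")) v@counts else v
    n <- length(x)
    if (n < 2L * outer + 1L)
        stop("vector length must be at least ", 2L * outer + 1L, " bins")
    cs <- cumsum(as.numeric(x))
    winSum <- function(h) {
        ## sum over [i-h, i+h] for i in (h+1)..(n-h)
        i <- seq(h + 1L, n - h)
        cs[i + h] - c(0, cs)[i - h]
    }
    S <- rep(NA_real_, n)
    i <- seq(outer + 1L, n - outer)
    num <- rep(NA_real_, n)
    den <- rep(NA_real_, n)
    num[seq(inner + 1L, n - inner)] <- winSum(inner)
    den[i] <- winSum(outer)
    S[i] <- ifelse(den[i] == 0, 0, num[i] / den[i])
    S
}

#' Center-weighted scores
#'
#' Convolution of the positioning scores with the Gaussian weight kernel:
#' \code{CS_i = sum_j S_{i+j} w_j} over the kernel span. \code{NA} wherever
#' any required S value is undefined.
#'
#' @param S positioning score vector (with NA at unsupported bins).
#' @param kernel weight kernel from \code{\link{weightKernel}}.
#' @return numeric vector of center-weighted scores (NA where undefined).
#' @export
centerWeighted <- function(S, kernel = weightKernel()) {
    n <- length(S)
    h <- (length(kernel) - 1L) %/% 2L
    CS <- rep(NA_real_, n)
    def <- !is.na(S)
    lo <- which(def)[1L]
    hi <- which(def)[length(which(def))]
    if (is.na(lo)) return(CS)
    if (hi - lo < 2L * h) return(CS)
    offs <- seq(-h, h)
    for (i in seq.int(lo + h, hi - h)) {
        seg <- S[i + offs]
        if (anyNA(seg)) next
        CS[i] <- sum(seg * kernel)
    }
    CS
}

#' Dynamic center of the valley
#'
#' Index of the minimum center-weighted score within +/- r bins of the
#' vector center: absorbs small offsets between the motif center and the
#' true protected center. Ties break to the index nearest the center, then
#' to the smaller index.
#'
#' @param CS center-weighted score vector.
#' @param r search half-width in bins (default 20).
#' @param center center bin index (default \code{(length(CS)+1)/2}).
#' @return integer bin index, or \code{NA} if CS is undefined anywhere in
#'   the search range (exception upstream).
#' @export
dynamicCenter <- function(CS, r = 20L, center = (length(CS) + 1L) %/% 2L) {
    idx <- seq(center - r, center + r)
    if (any(idx < 1L | idx > length(CS))) return(NA_integer_)
    seg <- CS[idx]
    if (anyNA(seg)) return(NA_integer_)
    cand <- idx[seg == min(seg)]
    cand <- cand[order(abs(cand - center), cand)]
    cand[1L]
}

#' Flanking summit positions
#'
#' Locates the maxima of the center-weighted score upstream and downstream
#' of the dynamic center within \code{search} bp of the vector center:
#' the assumed positions of the nucleosome dyads flanking the valley.
#' Ties break to the index nearest \code{dc}, then to the smaller index.
#'
#' @param CS center-weighted score vector.
#' @param dc dynamic center index.
#' @param search search range in bp on each side of the center
#'   (default 200).
#' @param bin bin size in bp.
#' @param center center bin index.
#' @return integer(2): \code{c(uS, dS)}, or NAs if a side is empty or CS
#'   undefined there (exception upstream).
#' @export
findSummits <- function(CS, dc, search = 200L, bin = 1L,
                        center = (length(CS) + 1L) %/% 2L) {
    sb <- search %/% bin
    bad <- c(uS = NA_integer_, dS = NA_integer_)
    if (is.na(dc)) return(bad)
    upIdx <- seq2(center - sb, dc - 1L)
    dnIdx <- seq2(dc + 1L, center + sb)
    if (!length(upIdx) || !length(dnIdx)) return(bad)
    if (any(c(upIdx, dnIdx) < 1L | c(upIdx, dnIdx) > length(CS)))
        return(bad)
    if (anyNA(CS[upIdx]) || anyNA(CS[dnIdx])) return(bad)
    pick <- function(idx) {
        seg <- CS[idx]
        cand <- idx[seg == max(seg)]
        cand <- cand[order(abs(cand - dc), cand)]
        cand[1L]
    }
    c(uS = pick(upIdx), dS = pick(dnIdx))
}

## seq() that returns integer(0) when from > to
seq2 <- function(from, to) {
    if (from > to) integer(0) else seq.int(from, to)
}

#' Summit distance
#'
#' Count-weighted mean distance (in bins) of raw midpoint counts from the
#' dynamic center, computed independently over the upstream ([uS, dc]) and
#' downstream ([dc, dS]) stretches and summed (\code{method = "split"},
#' the default). A side with zero counts contributes 0. The
#' \code{"pooled"} variant is a single weighted mean over [uS, dS], kept
#' for comparison.
#'
#' @param v a \linkS4class{PiledVector} or raw count vector.
#' @param uS,dc,dS upstream summit, dynamic center and downstream summit
#'   bin indices, \code{uS < dc < dS}.
#' @param method \code{"split"} or \code{"pooled"}.
#' @return non-negative summit distance in bins (= bp when bin = 1).
#' @export
summitDistance <- function(v, uS, dc, dS, method = c("split", "pooled")) {
    method <- match.arg(method)
    x <- if (is(v, "PiledVector")) v@counts else v
    if (is.na(uS) || is.na(dc) || is.na(dS)) return(0)
    stopifnot(uS < dc, dc < dS)
    wmean <- function(idx) {
        n <- x[idx]
        tot <- sum(n)
        if (tot == 0) 0 else sum(abs(idx - dc) * n) / tot
    }
    if (method == "pooled") {
        wmean(seq.int(uS, dS))
    } else {
        wmean(seq.int(uS, dc)) + wmean(seq.int(dc, dS))
    }
}

#' Low-coverage exception tag
#'
#' A piled-up vector with fewer than \code{minHitProportion} nonzero bins
#' is considered too sparse to support a summit-distance estimate; its SD
#' is recorded as 0 with this flag set.
#'
#' @param v a \linkS4class{PiledVector}.
#' @param minHitProportion threshold on the fraction of nonzero bins
#'   (default 0.05).
#' @return logical(1).
#' @export
tagException <- function(v, minHitProportion = 0.05) {
    hitProportion(v) < minHitProportion
}

#' Full valley geometry of one piled-up vector
#'
#' Runs positioning scores, center-weighted smoothing, dynamic-center and
#' summit detection and the summit distance on a piled-up vector, applying
#' the low-coverage exception rule. Offsets in the result are relative to
#' the vector center, in bins.
#'
#' @param v a \linkS4class{PiledVector}.
#' @param r dynamic-center search half-width in bins (default 20).
#' @param search summit search range in bp (default 200).
#' @param minHitProportion exception threshold (default 0.05).
#' @param sdMethod \code{"split"} (default) or \code{"pooled"}.
#' @param kernel weight kernel.
#' @return one-row data.frame: \code{dc}, \code{uS}, \code{dS} (bin offsets
#'   from the center; NA under exception), \code{sd},
#'   \code{hit_proportion}, \code{exception}.
#' @export
valleyGeometry <- function(v, r = 20L, search = 200L,
                           minHitProportion = 0.05,
                           sdMethod = c("split", "pooled"),
                           kernel = weightKernel()) {
    sdMethod <- match.arg(sdMethod)
    wb <- v@window %/% v@bin
    sb <- as.integer(search) %/% v@bin
    if (wb < sb + r + 173L)
        stop("window too small: need window/bin >= search/bin + r + 173 ",
             "(got ", wb, " < ", sb + r + 173L, ")")
    C <- wb + 1L
    hp <- hitProportion(v)
    res <- function(dc, uS, dS, sd, exc) {
        data.frame(dc = if (is.na(dc)) NA_integer_ else dc - C,
                   uS = if (is.na(uS)) NA_integer_ else uS - C,
                   dS = if (is.na(dS)) NA_integer_ else dS - C,
                   sd = sd, hit_proportion = hp, exception = exc)
    }
    if (tagException(v, minHitProportion))
        return(res(NA, NA, NA, 0, TRUE))
    S <- positioningScores(v)
    CS <- centerWeighted(S, kernel)
    dc <- dynamicCenter(CS, r = r, center = C)
    sm <- findSummits(CS, dc, search = search, bin = v@bin, center = C)
    if (is.na(dc) || anyNA(sm))
        return(res(NA, NA, NA, 0, TRUE))
    sd <- summitDistance(v, sm[["uS"]], dc, sm[["dS"]], method = sdMethod)
    res(dc, sm[["uS"]], sm[["dS"]], sd, FALSE)
}
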