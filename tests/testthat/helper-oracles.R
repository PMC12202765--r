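# Straight-line reference implementations used as independent oracles.
# They share nothing with the package internals beyond base R primitives.

oracleS <- function(x, inner = 15L, outer = 100L) {
    n <- length(x)
    S <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        if (i - outer < 1L || i + outer > n) next
        den <- sum(x[(i - outer):(i + outer)])
        num <- sum(x[(i - inner):(i + inner)])
        S[i] <- if (den == 0) 0 else num / den
    }
    S
}

oracleCS <- function(S, halfSpan = 73L, scale = 20) {
    n <- length(S)
    CS <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        if (i - halfSpan < 1L || i + halfSpan > n) next
        prods <- numeric(2L * halfSpan + 1L)
        ok <- TRUE
        for (j in -halfSpan:halfSpan) {
            s <- S[i + j]
            if (is.na(s)) { ok <- FALSE; break }
            prods[j + halfSpan + 1L] <- s * exp(-(j / scale)^2 / 2)
        }
        if (ok) CS[i] <- sum(prods)
    }
    CS
}

oracleDc <- function(CS, r = 20L, C = (length(CS) + 1L) %/% 2L) {
    best <- NA_integer_
    bestVal <- Inf
    for (i in (C - r):(C + r)) {
        v <- CS[i]
        if (is.na(v)) return(NA_integer_)
        take <- v < bestVal ||
            (v == bestVal && (abs(i - C) < abs(best - C) ||
                (abs(i - C) == abs(best - C) && i < best)))
        if (take) { best <- i; bestVal <- v }
    }
    best
}

oracleSummits <- function(CS, dc, search = 200L,
                          C = (length(CS) + 1L) %/% 2L) {
    pickMax <- function(idx) {
        best <- NA_integer_
        bestVal <- -Inf
        for (i in idx) {
            v <- CS[i]
            if (is.na(v)) return(NA_integer_)
            take <- v > bestVal ||
                (v == bestVal && (abs(i - dc) < abs(best - dc) ||
                    (abs(i - dc) == abs(best - dc) && i < best)))
            if (take) { best <- i; bestVal <- v }
        }
        best
    }
    if (is.na(dc) || dc - 1L < C - search || dc + 1L > C + search)
        return(c(NA_integer_, NA_integer_))
    c(pickMax((C - search):(dc - 1L)), pickMax((dc + 1L):(C + search)))
}

oracleSD <- function(x, uS, dc, dS) {
    up_num <- 0; up_den <- 0
    for (i in uS:dc) {
        up_num <- up_num + abs(i - dc) * x[i]
        up_den <- up_den + x[i]
    }
    dn_num <- 0; dn_den <- 0
    for (i in dc:dS) {
        dn_num <- dn_num + abs(i - dc) * x[i]
        dn_den <- dn_den + x[i]
    }
    (if (up_den == 0) 0 else up_num / up_den) +
        (if (dn_den == 0) 0 else dn_num / dn_den)
}

oraclePileUp <- function(mids, centers, window = 400L, bin = 1L) {
    nbins <- 2L * (window %/% bin) + 1L
    counts <- integer(nbins)
    for (ct in centers) {
        for (m in mids) {
            if (abs(m - ct) <= window) {
                idx <- (m - ct + window) %/% bin + 1L
                counts[idx] <- counts[idx] + 1L
            }
        }
    }
    counts
}

oracleCenterFlank <- function(mids, centers, centerBp = 100L,
                              flankBp = 200L) {
    nC <- 0L; nF <- 0L
    for (ct in centers) {
        for (m in mids) {
            d <- abs(m - ct)
            if (d <= centerBp) nC <- nC + 1L
            else if (d <= flankBp) nF <- nF + 1L
        }
    }
    list(nCenter = nC, nFlank = nF)
}

# two-sided Fisher p by full enumeration of the hypergeometric support,
# summing tables as or more extreme (prob <= observed, with the standard
# relative-error guard for floating-point ties)
oracleFisher <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    support <- max(0L, c1 - r2):min(r1, c1)
    probs <- dhyper(support, r1, r2, c1)
    pobs <- dhyper(a, r1, r2, c1)
    sum(probs[probs <= pobs * (1 + 1e-7)])
}

# all permutations of 1..n (n small), for exhaustive assignment search
allPerms <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (p in allPerms(n - 1L)) {
        for (k in seq_len(n)) {
            out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
        }
    }
    out
}

oracleBestAccuracy <- function(tab) {
    # tab: square matrix truth x pred; best diagonal mass over mappings
    n <- nrow(tab)
    best <- -Inf
    for (p in allPerms(n)) {
        tot <- sum(tab[cbind(seq_len(n), p)])
        if (tot > best) best <- tot
    }
    best / sum(tab)
}

# convenience constructors --------------------------------------------------

makeMidpointSet <- function(cell, mids, mode = "mnase") {
    # mids: named list chrom -> positions, or bare vector (-> chr1)
    if (!is.list(mids)) mids <- list(chr1 = mids)
    mids <- lapply(mids, function(v) sort(as.integer(v)))
    new("MidpointSet", cellId = cell, mode = mode, midpoints = mids,
        nDropped = 0L, nInput = sum(lengths(mids)))
}

makeSiteSet <- function(motif, centers, chrom = "chr1", strand = "+") {
    newSiteSet(motif, data.frame(chrom = chrom, center = centers,
                                 strand = strand), "imported")
}

makePiled <- function(counts, bin = 1L) {
    window <- as.integer((length(counts) - 1L) / 2 * bin)
    new("PiledVector", counts = as.integer(counts), window = window,
        bin = as.integer(bin), nSites = 1L)
}

# a small, quick scenario for pipeline-level tests
smallScenario <- function(seed = 42L, cellsPerType = 12L,
                          coverage = 1500L, nMotifs = 8L,
                          sitesPerMotif = 30L) {
    cfg <- scenarioConfig(nTypes = 2L, cellsPerType = cellsPerType,
                          nMotifs = nMotifs,
                          sitesPerMotif = sitesPerMotif,
                          genomeLength = 1e6, coverage = coverage,
                          seed = seed)
    simulateScenario(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
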