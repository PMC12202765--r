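#' Scenario configuration for the synthetic scMNase-seq generator
#'
#' Describes a ground-truthed scenario: cell types differ in the depth and
#' width of the nucleosome-free valley planted around the sites of their
#' signature motifs. Defaults describe a sparse single-cell regime:
#' phased nucleosome arrays (180 bp spacing, 10 bp dyad jitter) flanking a
#' valley of half-width 150 bp (active) or 80 bp (inactive), 2000
#' nucleosome-sized fragments per cell, 10\% uniform background noise.
#'
#' Each type gets \code{floor(nMotifs / (nTypes + 1))} signature motifs at
#' \code{depthActive}; all other (type, motif) pairs sit at
#' \code{depthInactive}. A fragment attributed to a site falls in the
#' valley interior with probability \code{1 - depth}, otherwise on a
#' flanking array dyad.
#'
#' @param nTypes number of cell types (default 3).
#' @param cellsPerType cells per type (default 50).
#' @param nMotifs number of motifs (default 20).
#' @param sitesPerMotif sites per motif (default 50).
#' @param genomeLength virtual genome length in bp (default 5e6).
#' @param spacing nucleosome spacing in bp (default 180).
#' @param fragLenRange inclusive fragment-length range (default 140-180).
#' @param coverage expected fragments per cell (default 2000).
#' @param noiseFraction fraction of uniformly placed fragments
#'   (default 0.1).
#' @param jitterSd dyad jitter standard deviation in bp (default 10).
#' @param depthActive,depthInactive planted valley depths (defaults 0.8
#'   and 0.1; contrast 0.7).
#' @param halfWidthActive,halfWidthInactive valley half-widths in bp
#'   (defaults 150 and 80).
#' @param seed RNG seed.
#' @return a list of class \code{"ScenarioConfig"} including the
#'   per-(type, motif) \code{depth} and \code{halfWidth} matrices.
#' @export
scenarioConfig <- function(nTypes = 3L, cellsPerType = 50L, nMotifs = 20L,
                           sitesPerMotif = 50L, genomeLength = 5e6,
                           spacing = 180L, fragLenRange = c(140L, 180L),
                           coverage = 2000L, noiseFraction = 0.1,
                           jitterSd = 10, depthActive = 0.8,
                           depthInactive = 0.1, halfWidthActive = 150L,
                           halfWidthInactive = 80L, seed = 1L) {
    stopifnot(nTypes >= 1L, cellsPerType >= 1L, nMotifs >= 1L,
              sitesPerMotif >= 1L, noiseFraction >= 0, noiseFraction <= 1,
              depthActive >= 0, depthActive <= 1,
              depthInactive >= 0, depthInactive <= 1)
    motifs <- sprintf("motif%02d", seq_len(nMotifs))
    types <- sprintf("type%d", seq_len(nTypes))
    depth <- matrix(depthInactive, nTypes, nMotifs,
                    dimnames = list(types, motifs))
    halfWidth <- matrix(halfWidthInactive, nTypes, nMotifs,
                        dimnames = list(types, motifs))
    nSig <- max(1L, nMotifs %/% (nTypes + 1L))
    for (t in seq_len(nTypes)) {
        cols <- seq.int((t - 1L) * nSig + 1L, min(t * nSig, nMotifs))
        depth[t, cols] <- depthActive
        halfWidth[t, cols] <- halfWidthActive
    }
    structure(list(
        nTypes = nTypes, cellsPerType = cellsPerType, nMotifs = nMotifs,
        sitesPerMotif = sitesPerMotif, genomeLength = genomeLength,
        spacing = spacing, fragLenRange = fragLenRange,
        coverage = coverage, noiseFraction = noiseFraction,
        jitterSd = jitterSd, depth = depth, halfWidth = halfWidth,
        types = types, motifs = motifs, nSignature = nSig, seed = seed),
        class = "ScenarioConfig")
}

#' Signature motifs planted for each cell type
#'
#' @param config a \code{"ScenarioConfig"}.
#' @return named list: per type, the motif ids planted at
#'   \code{depthActive}.
#' @export
signatureMotifs <- function(config) {
    lapply(stats::setNames(seq_len(config$nTypes), config$types),
           function(t) config$motifs[config$depth[t, ] ==
                                     max(config$depth)])
}

#' Generate a synthetic scMNase-seq scenario
#'
#' Places non-overlapping sites on a virtual genome (single chromosome
#' \code{"chrS"}), assigns them to motifs at random, and draws per-cell
#' fragments from the planted valley/array mixture of the cell's type.
#' Fragment lengths are uniform over the configured range, so every
#' fragment passes the mnase length filter; midpoints reproduce the drawn
#' dyad positions exactly.
#'
#' @param config a \code{"ScenarioConfig"}.
#' @return list of class \code{"NucScenario"}: \code{fragments}
#'   (data.table \code{chrom}, \code{start}, \code{end}, \code{cell}),
#'   \code{siteSets} (named list of \linkS4class{SiteSet}),
#'   \code{regions} (accessible-region data.frame), \code{truth} (named
#'   cell -> type vector) and \code{config}.
#' @export
simulateScenario <- function(config) {
    stopifnot(inherits(config, "ScenarioConfig"))
    set.seed(config$seed)
    nSites <- config$nMotifs * config$sitesPerMotif
    gap <- floor(config$genomeLength / (nSites + 1L))
    if (gap < 1200L)
        stop("genome too small to place ", nSites,
             " non-overlapping sites (need >= ",
             1200L * (nSites + 1L), " bp)")
    centers <- as.integer(gap * seq_len(nSites))
    siteMotif <- sample(rep(config$motifs, config$sitesPerMotif))
    strand <- sample(c("+", "-"), nSites, replace = TRUE)
    siteSets <- lapply(stats::setNames(config$motifs, config$motifs),
        function(mo) {
            idx <- siteMotif == mo
            newSiteSet(mo, data.frame(chrom = "chrS",
                center = centers[idx], strand = strand[idx]),
                "synthetic")
        })
    regions <- data.frame(chrom = "chrS", start = centers - 300L,
                          end = centers + 300L)

    cells <- as.vector(vapply(seq_len(config$nTypes), function(t)
        sprintf("%s_cell%03d", config$types[t],
                seq_len(config$cellsPerType)),
        character(config$cellsPerType)))
    truth <- stats::setNames(rep(config$types,
                                 each = config$cellsPerType), cells)

    lenLo <- config$fragLenRange[1L]
    lenHi <- config$fragLenRange[2L]
    frags <- vector("list", length(cells))
    for (ci in seq_along(cells)) {
        t <- match(truth[[ci]], config$types)
        n <- stats::rpois(1L, config$coverage)
        isNoise <- stats::runif(n) < config$noiseFraction
        nN <- sum(isNoise)
        nS <- n - nN
        mid <- integer(n)
        if (nN)
            mid[isNoise] <- as.integer(floor(stats::runif(nN, 1,
                config$genomeLength)))
        if (nS) {
            si <- sample.int(nSites, nS, replace = TRUE)
            mo <- match(siteMotif[si], config$motifs)
            d <- config$depth[cbind(t, mo)]
            h <- config$halfWidth[cbind(t, mo)]
            inValley <- stats::runif(nS) < (1 - d)
            off <- integer(nS)
            nv <- sum(inValley)
            if (nv)
                off[inValley] <- as.integer(round(stats::runif(nv,
                    -h[inValley], h[inValley])))
            na <- nS - nv
            if (na) {
                ring <- sample(0:1, na, replace = TRUE)
                side <- sample(c(-1L, 1L), na, replace = TRUE)
                off[!inValley] <- as.integer(round(
                    side * (h[!inValley] + ring * config$spacing) +
                    stats::rnorm(na, 0, config$jitterSd)))
            }
            mid[!isNoise] <- centers[si] + off
        }
        len <- sample(seq.int(lenLo, lenHi), n, replace = TRUE)
        start <- pmax(0L, mid - len %/% 2L)
        frags[[ci]] <- data.table::data.table(chrom = "chrS",
            start = start, end = start + len, cell = cells[ci])
    }
    structure(list(fragments = data.table::rbindlist(frags),
                   siteSets = siteSets, regions = regions, truth = truth,
                   config = config),
              class = "NucScenario")
}

#' Write a scenario to disk in the formats the pipeline reads
#'
#' Emits \code{fragments/<cell>.bed} (BED3 per cell),
#' \code{fragments.tsv} (4-column multi-cell fragments file),
#' \code{sites.bed} (BED6, name = motif id), \code{regions.bed} (BED3),
#' \code{truth.tsv} and \code{config.json}.
#'
#' @param scenario a \code{"NucScenario"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
    dir.create(file.path(dir, "fragments"), recursive = TRUE,
               showWarnings = FALSE)
    fr <- scenario$fragments
    writeFragments(fr, file.path(dir, "fragments.tsv"),
                   "multi_cell_fragments")
    for (cl in unique(fr$cell))
        writeFragments(fr[fr$cell == cl, ],
                       file.path(dir, "fragments", paste0(cl, ".bed")),
                       "per_cell_bed")
    writeSitesBED(scenario$siteSets, file.path(dir, "sites.bed"))
    data.table::fwrite(scenario$regions, file.path(dir, "regions.bed"),
                       sep = "\t", col.names = FALSE, quote = FALSE)
    data.table::fwrite(data.frame(cell_id = names(scenario$truth),
                                  type = scenario$truth),
                       file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE)
    cfg <- scenario$config
    cfg$depth <- NULL
    cfg$halfWidth <- NULL
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE)
    invisible(dir)
}

#' Expected nucleosome-free score under a scenario
#'
#' Analytic companion to the simulator: integrates the planted mixture
#' densities to get the expected center (<= 100 bp) and flank
#' (100-200 bp) masses per site for a (type, motif) pair, and the
#' background mass over all sites, giving the expected NS for
#' parameter-recovery checks. Uses the continuous mixture (uniform valley,
#' Gaussian dyad rings, uniform noise); finite-coverage sampling noise is
#' not modelled.
#'
#' @param config a \code{"ScenarioConfig"}.
#' @param type type label or index.
#' @param motif motif label or index.
#' @return list with \code{ns}, \code{Ft}, \code{Fb}.
#' @export
expectedNS <- function(config, type, motif) {
    if (is.character(type)) type <- match(type, config$types)
    if (is.character(motif)) motif <- match(motif, config$motifs)
    zoneMass <- function(d, h, lo, hi) {
        ## mass of |x| in (lo, hi] for one structured fragment at a site
        unif <- function(a, b) {
            ## valley: |x| ~ U(0, h) in magnitude (symmetric uniform)
            (min(b, h) - min(a, h)) / h
        }
        ring <- function(mu) {
            (stats::pnorm(hi, mu, config$jitterSd) -
             stats::pnorm(lo, mu, config$jitterSd)) +
            (stats::pnorm(-lo, mu, config$jitterSd) -
             stats::pnorm(-hi, mu, config$jitterSd))
        }
        ## ring() already averages the two sides (each side's Gaussian
        ## contributes its own zone mass); rings are equiprobable
        mus <- h + (0:1) * config$spacing
        (1 - d) * unif(lo, hi) +
            d * sum(vapply(mus, ring, numeric(1))) / 2
    }
    siteMass <- function(t, m, lo, hi) {
        d <- config$depth[t, m]
        h <- config$halfWidth[t, m]
        s <- (1 - config$noiseFraction) /
            (config$nMotifs * config$sitesPerMotif)
        lam <- config$noiseFraction / config$genomeLength
        s * zoneMass(d, h, lo, hi) + lam * 2 * (hi - lo)
    }
    cT <- siteMass(type, motif, 0, 100)
    fT <- siteMass(type, motif, 100, 200)
    cB <- sum(vapply(seq_len(config$nMotifs), function(m)
        siteMass(type, m, 0, 100), numeric(1)))
    fB <- sum(vapply(seq_len(config$nMotifs), function(m)
        siteMass(type, m, 100, 200), numeric(1)))
    Ft <- cT / (cT + fT)
    Fb <- cB / (cB + fB)
    list(ns = log2(Fb) - log2(Ft), Ft = Ft, Fb = Fb)
}
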