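jasparText <- function(id = "MA0001.1", name = "TFX",
                       rows = c(A = "4 19 0 0 0 0 0 4",
                                C = "16 0 20 0 0 0 0 4",
                                G = "0 1 0 20 0 20 0 8",
                                T = "0 0 0 0 20 0 20 4")) {
    c(paste(">", id, name),
      sprintf("%s  [ %s ]", names(rows), rows))
}

test_that("JASPAR parsing normalises rows and keeps file order", {
    f <- withr::local_tempfile(fileext = ".jaspar")
    # second record with shuffled row order
    writeLines(c(jasparText(),
                 jasparText(id = "MA0002.1", name = "TFY",
                            rows = c(T = "0 0 5 1", G = "0 5 0 1",
                                     C = "5 0 0 1", A = "1 1 1 1"))), f)
    pfms <- parseJaspar(f)
    expect_named(pfms, c("MA0001.1", "MA0002.1"))
    expect_equal(ncol(pfms[[1]]@counts), 8L)
    expect_identical(rownames(pfms[[2]]@counts), c("A", "C", "G", "T"))
    expect_equal(pfms[[2]]@counts["T", ], c(0, 0, 5, 1))
})

test_that("a missing base row is reported with the motif id", {
    f <- withr::local_tempfile(fileext = ".jaspar")
    writeLines(c(">MA0009.9 BAD", "A [ 1 2 3 4 ]", "C [ 1 2 3 4 ]",
                 "G [ 1 2 3 4 ]"), f)
    expect_error(parseJaspar(f), "MA0009.9.*missing.*T")
})

strongPFM <- function(seqstr) {
    # PFM that matches seqstr essentially uniquely
    bases <- strsplit(seqstr, "")[[1]]
    cm <- matrix(0, 4, length(bases),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(bases)) cm[bases[j], j] <- 100
    cm <- cm + 0.01
    new("MotifPFM", id = "planted", name = "planted", counts = cm)
}

test_that("a planted motif is found once, on the correct strand", {
    pfm <- strongPFM("ACGTACGT")
    set.seed(1)
    bgseq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                          prob = c(.3, .2, .2, .3)), collapse = "")
    genome <- Biostrings::DNAStringSet(c(
        chrA = paste0(substr(bgseq, 1, 100), "ACGTACGT",
                      substr(bgseq, 101, 200))))
    ss <- scanGenome(pfm, genome, pvalue = 1e-4, bg = rep(0.25, 4))
    st <- siteTable(ss)
    # window starts at 0-based 100, width 8 -> floor midpoint 103
    expect_true(nrow(st) >= 1L)
    expect_true(any(st$center == 103L & st$strand == "+"))

    # reverse complement planted instead
    genome2 <- Biostrings::DNAStringSet(c(
        chrA = paste0(substr(bgseq, 1, 100),
                      as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString("ACGTACGT"))),
                      substr(bgseq, 101, 200))))
    st2 <- siteTable(scanGenome(pfm, genome2, pvalue = 1e-4,
                                bg = rep(0.25, 4)))
    expect_true(any(st2$center == 103L & st2$strand == "-"))
})

test_that("scanning a reverse-complemented genome mirrors the hits", {
    pfm <- strongPFM("ACGGTA")
    set.seed(5)
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    s <- paste0(substr(s, 1, 150), "ACGGTA", substr(s, 151, 400))
    g1 <- Biostrings::DNAStringSet(c(chr = s))
    g2 <- Biostrings::DNAStringSet(c(chr = as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))))
    st1 <- siteTable(scanGenome(pfm, g1, bg = rep(0.25, 4)))
    st2 <- siteTable(scanGenome(pfm, g2, bg = rep(0.25, 4)))
    L <- nchar(s)
    # a hit window [a, a+6) maps to [L-a-6, L-a); centers are floor
    # midpoints so mirrored centers satisfy c2 = L - 1 - c1 - 1 for even
    # motifs (floor asymmetry): compare the full sets
    mirror <- sort((L - 1L) - st1$center - 1L)
    expect_equal(sort(st2$center), mirror)
    expect_setequal(paste(st2$strand), ifelse(st1$strand == "+", "-",
                                              "+"))
})

test_that("DP threshold tail equals brute-force enumeration for L = 6", {
    set.seed(11)
    cm <- matrix(rpois(24, 6) + 1, 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
    pfm <- new("MotifPFM", id = "m", name = "m", counts = cm)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    sc <- scValley:::pfmScoreMatrix(pfm, bg)
    thr <- pfmScoreThreshold(sc, bg, pvalue = 1e-3)
    # enumerate all 4^6 windows
    grid <- as.matrix(expand.grid(rep(list(1:4), 6)))
    scores <- rowSums(matrix(sc[cbind(as.vector(grid),
        rep(1:6, each = nrow(grid)))], nrow(grid)))
    probs <- apply(matrix(bg[grid], nrow(grid)), 1, prod)
    # discretise exactly as the DP does
    g <- 1e-3
    iscores <- rowSums(matrix(round(sc / g)[cbind(as.vector(grid),
        rep(1:6, each = nrow(grid)))], nrow(grid)))
    tail <- sum(probs[iscores >= round(thr$threshold / g)])
    expect_equal(tail, thr$tailProb, tolerance = 1e-12)
    expect_true(thr$tailProb <= 1e-3)
    # threshold is the smallest such score
    below <- sum(probs[iscores >= round(thr$threshold / g) - 1L])
    expect_gt(below, 1e-3)
})

test_that("accessibility filtering recentres regions and takes the union", {
    ss <- makeSiteSet("m1", c(500L, 611L, 209L, 210L))
    regions <- data.frame(chrom = "chr1", start = 400L, end = 420L)
    # center 410, extended [210, 610)
    kept <- siteTable(filterByAccessibility(ss, regions, extend = 200L))
    expect_setequal(kept$center, c(500L, 210L))
})

test_that("accessibility filtering matches a brute-force membership scan", {
    set.seed(3)
    for (rep in 1:5) {
        ss <- makeSiteSet("m", sort(sample.int(5000, 80)))
        regions <- data.frame(chrom = "chr1",
                              start = sort(sample.int(4500, 15)))
        regions$end <- regions$start + sample(50:400, 15, TRUE)
        ext <- 100L
        kept <- siteTable(filterByAccessibility(ss, regions,
                                                extend = ext))$center
        ctr <- (regions$start + regions$end) %/% 2L
        naive <- vapply(siteTable(ss)$center, function(x)
            any(x >= ctr - ext & x < ctr + ext), logical(1))
        expect_setequal(kept, siteTable(ss)$center[naive])
    }
})

test_that("accessibility filtering is idempotent", {
    set.seed(9)
    ss <- makeSiteSet("m", sort(sample.int(3000, 60)))
    regions <- data.frame(chrom = "chr1", start = c(100L, 900L, 2000L),
                          end = c(300L, 1500L, 2600L))
    once <- filterByAccessibility(ss, regions)
    twice <- filterByAccessibility(once, regions)
    expect_identical(siteTable(once), siteTable(twice))
})

test_that("site BED6 round trip preserves sets", {
    ss <- list(m1 = makeSiteSet("m1", c(10L, 50L)),
               m2 = makeSiteSet("m2", c(30L), strand = "-"))
    f <- withr::local_tempfile(fileext = ".bed")
    writeSitesBED(ss, f)
    back <- readSitesBED(f)
    expect_setequal(names(back), c("m1", "m2"))
    expect_equal(siteTable(back$m1)$center, c(10L, 50L))
    expect_equal(siteTable(back$m2)$strand, "-")
})
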