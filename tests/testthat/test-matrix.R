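geomDF <- function(sdv, ex) {
    # sdv, ex: cells x motifs matrices (cells in rows for readability)
    cells <- rownames(sdv)
    motifs <- colnames(sdv)
    do.call(rbind, lapply(cells, function(cl)
        data.frame(cell = cl, motif = motifs, sd = sdv[cl, ],
                   exception = ex[cl, ], row.names = NULL)))
}

test_that("matrix assembly fills values and mask, keeps order", {
    sdv <- matrix(c(3, 0, 5, 2), 2, byrow = TRUE,
                  dimnames = list(c("c1", "c2"), c("m1", "m2")))
    ex <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, byrow = TRUE,
                 dimnames = dimnames(sdv))
    nme <- assembleMatrix(geomDF(sdv, ex))
    expect_identical(colnames(nme), c("c1", "c2"))
    expect_identical(rownames(nme), c("m1", "m2"))
    expect_equal(sdMatrix(nme)["m2", "c1"], 0)
    expect_identical(unname(exceptionMask(nme)["m2", "c1"]), TRUE)
    expect_equal(sum(exceptionMask(nme)), 1L)
})

test_that("duplicate and missing pairs are reported by name", {
    g <- data.frame(cell = c("c1", "c1"), motif = c("m1", "m1"),
                    sd = c(1, 2), exception = FALSE)
    expect_error(assembleMatrix(g), "duplicate.*c1.*m1")
    g2 <- data.frame(cell = c("c1", "c1", "c2"),
                     motif = c("m1", "m2", "m1"),
                     sd = 1, exception = FALSE)
    expect_error(assembleMatrix(g2), "missing.*c2.*m2")
})

test_that("QC filtering drops cells then motifs with strict cutoffs", {
    cells <- sprintf("c%02d", 1:10)
    motifs <- sprintf("m%02d", 1:10)
    # cell pass: strict > 0.70
    ex <- matrix(FALSE, 10, 10, dimnames = list(cells, motifs))
    ex["c01", 1:8] <- TRUE            # 0.8 > 0.7 -> dropped
    ex["c02", 1:7] <- TRUE            # 0.7, not > 0.7 -> retained
    sdv <- matrix(1, 10, 10, dimnames = dimnames(ex))
    sdv[ex] <- 0
    f <- filterMatrix(assembleMatrix(geomDF(sdv, ex)))
    expect_false("c01" %in% colnames(f))
    expect_true("c02" %in% colnames(f))
    expect_equal(nrow(f), 10L)

    # motif pass: strict > 0.90, evaluated over retained cells
    ex2 <- matrix(FALSE, 10, 10,
                  dimnames = list(cells, c(sprintf("m%02d", 1:8),
                                           "mA", "mB")))
    ex2[1:9, "mA"] <- TRUE            # 0.9, not > 0.9 -> retained
    ex2[1:10, "mB"] <- TRUE           # 1.0 > 0.9 -> dropped
    sdv2 <- matrix(1, 10, 10, dimnames = dimnames(ex2))
    sdv2[ex2] <- 0
    f2 <- filterMatrix(assembleMatrix(geomDF(sdv2, ex2)))
    expect_equal(ncol(f2), 10L)       # no cell above 0.7
    expect_true("mA" %in% rownames(f2))
    expect_false("mB" %in% rownames(f2))
})

test_that("QC filtering equals a naive two-pass scan on random masks", {
    set.seed(13)
    for (rep in 1:5) {
        nc <- 12L; nm <- 9L
        ex <- matrix(runif(nc * nm) < 0.5, nc, nm,
                     dimnames = list(sprintf("c%d", 1:nc),
                                     sprintf("m%d", 1:nm)))
        sdv <- matrix(rexp(nc * nm), nc, nm, dimnames = dimnames(ex))
        sdv[ex] <- 0
        keepC <- rowMeans(ex) <= 0.7
        if (!any(keepC)) next
        keepM <- colMeans(ex[keepC, , drop = FALSE]) <= 0.9
        f <- tryCatch(filterMatrix(assembleMatrix(geomDF(sdv, ex))),
                      error = function(e) NULL)
        if (!any(keepM)) {
            expect_null(f)
        } else {
            expect_setequal(colnames(f), rownames(ex)[keepC])
            expect_setequal(rownames(f), colnames(ex)[keepM])
        }
    }
})

test_that("dropping every cell is an error with advice", {
    ex <- matrix(TRUE, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
    sdv <- matrix(0, 3, 4, dimnames = dimnames(ex))
    expect_error(filterMatrix(assembleMatrix(geomDF(sdv, ex))),
                 "maxCellException")
})

test_that("winsorisation clamps at type-7 percentiles per motif", {
    sdv <- matrix(c(0, 1, 2, 3, 100), 5, 1,
                  dimnames = list(sprintf("c%d", 1:5), "m1"))
    ex <- matrix(FALSE, 5, 1, dimnames = dimnames(sdv))
    nme <- assembleMatrix(geomDF(sdv, ex))
    w <- winsorizeMotifs(nme, lower = 1, upper = 80)
    q <- quantile(c(0, 1, 2, 3, 100), c(0.01, 0.8), type = 7,
                  names = FALSE)
    expect_equal(unname(sdMatrix(w)["m1", ]),
                 pmin(pmax(c(0, 1, 2, 3, 100), q[1]), q[2]))
    # identity limits and constant columns
    w2 <- winsorizeMotifs(nme, lower = 0, upper = 100)
    expect_equal(sdMatrix(w2), sdMatrix(nme))
    sdv3 <- matrix(7, 5, 1, dimnames = dimnames(sdv))
    nme3 <- assembleMatrix(geomDF(sdv3, ex))
    expect_equal(sdMatrix(winsorizeMotifs(nme3, 5, 95)), sdMatrix(nme3))
})

test_that("CV selection uses sample sd over mean and is scale invariant", {
    sdv <- cbind(m1 = rep(4, 6), m2 = c(0, 2, 0, 2, 0, 2),
                 m3 = c(0, 8, 0, 8, 0, 8))
    rownames(sdv) <- sprintf("c%d", 1:6)
    ex <- matrix(FALSE, 6, 3, dimnames = dimnames(sdv))
    nme <- assembleMatrix(geomDF(sdv, ex))
    kept <- cvSelect(nme, minCV = 0.5)
    # constant -> CV 0; two-point columns CV = sd/mean > 0.5
    expect_false("m1" %in% rownames(kept))
    expect_setequal(rownames(kept), c("m2", "m3"))  # scale invariance
    cv <- SummarizedExperiment::rowData(kept)$cv
    expect_equal(unname(cv), rep(sd(c(0, 2, 0, 2, 0, 2)) / 1, 2),
                 tolerance = 1e-12)
})

test_that("CV selection equals direct computation on random columns", {
    set.seed(17)
    sdv <- matrix(rexp(8 * 10), 8, 10,
                  dimnames = list(sprintf("c%d", 1:8),
                                  sprintf("m%d", 1:10)))
    ex <- matrix(FALSE, 8, 10, dimnames = dimnames(sdv))
    nme <- assembleMatrix(geomDF(sdv, ex))
    kept <- rownames(cvSelect(nme, minCV = 0.8))
    naive <- colnames(sdv)[apply(sdv, 2, function(x)
        sd(x) / mean(x) > 0.8)]
    expect_setequal(kept, naive)
})

test_that("tree clustering recovers well-separated blobs and yields k groups", {
    set.seed(23)
    n <- 20L
    sdv <- rbind(matrix(rnorm(n * 5, 10, 0.5), n),
                 matrix(rnorm(n * 5, 30, 0.5), n))
    rownames(sdv) <- sprintf("c%02d", 1:(2 * n))
    colnames(sdv) <- sprintf("m%d", 1:5)
    ex <- matrix(FALSE, 2 * n, 5, dimnames = dimnames(sdv))
    nme <- assembleMatrix(geomDF(sdv, ex))
    cr <- clusterCells(nme, "tree", k = 2L)
    lab <- clusterLabels(cr)
    truth <- rep(1:2, each = n)
    expect_equal(scoreClustering(lab, truth)$accuracy, 1)
    expect_equal(sort(unique(lab)), 1:2)
    # k = n cells -> singletons
    crn <- clusterCells(nme, "tree", k = 2L * n)
    expect_equal(length(unique(clusterLabels(crn))), 2L * n)
    expect_error(clusterCells(nme, "tree", k = 2L * n + 1L), "'k'")
    # identical rows still split deterministically
    sdvc <- matrix(5, 6, 3, dimnames = list(sprintf("c%d", 1:6),
                                            sprintf("m%d", 1:3)))
    exc <- matrix(FALSE, 6, 3, dimnames = dimnames(sdvc))
    nmec <- assembleMatrix(geomDF(sdvc, exc))
    l1 <- clusterLabels(clusterCells(nmec, "tree", k = 2L))
    l2 <- clusterLabels(clusterCells(nmec, "tree", k = 2L))
    expect_identical(l1, l2)
    expect_equal(length(unique(l1)), 2L)
})

test_that("graph clustering is seeded and separates strong blobs", {
    set.seed(29)
    n <- 15L
    sdv <- rbind(matrix(rnorm(n * 6, 5, 0.3), n),
                 matrix(rnorm(n * 6, 25, 0.3), n))
    rownames(sdv) <- sprintf("c%02d", 1:(2 * n))
    colnames(sdv) <- sprintf("m%d", 1:6)
    ex <- matrix(FALSE, 2 * n, 6, dimnames = dimnames(sdv))
    nme <- assembleMatrix(geomDF(sdv, ex))
    cr1 <- clusterCells(nme, "graph", kNN = 5L, seed = 3L)
    cr2 <- clusterCells(nme, "graph", kNN = 5L, seed = 3L)
    expect_identical(clusterLabels(cr1), clusterLabels(cr2))
    truth <- rep(1:2, each = n)
    expect_gte(scoreClustering(clusterLabels(cr1), truth)$accuracy,
               0.95)
})

test_that("embedding returns one coordinate row per cell, deterministically", {
    set.seed(37)
    sdv <- matrix(rnorm(12, 10), 4, 3,
                  dimnames = list(sprintf("c%d", 1:4),
                                  sprintf("m%d", 1:3)))
    ex <- matrix(FALSE, 4, 3, dimnames = dimnames(sdv))
    nme <- assembleMatrix(geomDF(sdv, ex))
    expect_warning(e1 <- embedCells(nme, seed = 1L), "PCA")
    expect_warning(e2 <- embedCells(nme, seed = 1L), "PCA")
    expect_equal(e1, e2)
    expect_equal(nrow(e1), 4L)
    expect_named(e1, c("cell", "dim1", "dim2"))
})

test_that("matrix and cluster TSV round trips preserve content", {
    sdv <- matrix(c(1.5, 0, 2, 3.25), 2,
                  dimnames = list(c("cA", "cB"), c("m1", "m2")))
    ex <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2,
                 dimnames = dimnames(sdv))
    sdv[ex] <- 0
    nme <- assembleMatrix(geomDF(sdv, ex))
    f <- withr::local_tempfile(fileext = ".tsv")
    fe <- withr::local_tempfile(fileext = ".tsv")
    writeMatrixTSV(nme, f, fe)
    back <- readMatrixTSV(f, fe)
    expect_equal(sdMatrix(back), sdMatrix(nme))
    expect_equal(exceptionMask(back), exceptionMask(nme))

    cr <- new("ClusterResult",
              labels = setNames(c(1L, 2L), c("cA", "cB")),
              method = "tree", params = list(k = 2L))
    fc <- withr::local_tempfile(fileext = ".tsv")
    writeClusterTSV(cr, fc)
    expect_equal(readClusterTSV(fc), clusterLabels(cr))
})
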