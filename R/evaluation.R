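## O(n^3) shortest-augmenting-path solver for the square min-cost
## assignment problem; returns, for each row, its assigned column.
.hungarian <- function(cost) {
    n <- nrow(cost)
    stopifnot(ncol(cost) == n)
    u <- numeric(n + 1L)
    v <- numeric(n + 1L)
    p <- integer(n + 1L)   # p[j+1] = row matched to column j (0 = none)
    way <- integer(n + 1L)
    for (i in seq_len(n)) {
        p[1L] <- i
        j0 <- 0L
        minv <- rep(Inf, n + 1L)
        used <- logical(n + 1L)
        repeat {
            used[j0 + 1L] <- TRUE
            i0 <- p[j0 + 1L]
            delta <- Inf
            j1 <- 0L
            for (j in seq_len(n)) {
                if (used[j + 1L]) next
                cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
                if (cur < minv[j + 1L]) {
                    minv[j + 1L] <- cur
                    way[j + 1L] <- j0
                }
                if (minv[j + 1L] < delta) {
                    delta <- minv[j + 1L]
                    j1 <- j
                }
            }
            for (j in 0:n) {
                if (used[j + 1L]) {
                    u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
                    v[j + 1L] <- v[j + 1L] - delta
                } else {
                    minv[j + 1L] <- minv[j + 1L] - delta
                }
            }
            j0 <- j1
            if (p[j0 + 1L] == 0L) break
        }
        repeat {
            j1 <- way[j0 + 1L]
            p[j0 + 1L] <- p[j1 + 1L]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    ans <- integer(n)
    for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
    ans
}

#' Optimal matching of predicted clusters to truth classes
#'
#' Builds the truth x prediction contingency table, pads it to a square
#' with zeros when the numbers of classes differ, and solves the
#' assignment that maximises the total diagonal count (Hungarian method).
#'
#' @param pred vector of predicted cluster labels.
#' @param truth vector of true class labels (same length and order).
#' @return list with \code{mapping} (named: predicted level -> matched
#'   truth level, NA for padded entries), \code{table} (raw contingency
#'   table) and \code{matched} (square table with predicted columns
#'   reordered onto the matched truth rows).
#' @export
matchLabels <- function(pred, truth) {
    stopifnot(length(pred) == length(truth), length(pred) > 0L)
    tl <- as.character(sort(unique(truth)))
    pl <- as.character(sort(unique(pred)))
    tab <- table(factor(truth, levels = tl), factor(pred, levels = pl))
    d <- max(length(tl), length(pl))
    m <- matrix(0, d, d)
    m[seq_along(tl), seq_along(pl)] <- tab
    assign <- .hungarian(max(m) - m)   # rows = truth, maximise diagonal
    ## column j of 'matched' holds the predicted cluster assigned to truth
    ## class j
    colOfTruth <- assign
    matched <- m[, colOfTruth, drop = FALSE]
    dimnames(matched) <- list(
        truth = c(tl, rep(NA_character_, d - length(tl))),
        pred = c(pl, rep(NA_character_, d - length(pl)))[colOfTruth])
    mapping <- stats::setNames(rep(NA_character_, length(pl)), pl)
    for (ti in seq_along(tl)) {
        pj <- colOfTruth[ti]
        if (pj <= length(pl)) mapping[pl[pj]] <- tl[ti]
    }
    list(mapping = mapping, table = tab, matched = matched)
}

#' Score a clustering against ground truth
#'
#' Overall accuracy is the fraction of cells on the diagonal of the
#' optimally matched confusion matrix; Cohen's kappa corrects it for
#' chance agreement, \code{kappa = (p_o - p_e) / (1 - p_e)} with
#' \code{p_e = sum_c row_c * col_c / N^2} on the matched matrix.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @return list with \code{confusion} (matched matrix),
#'   \code{accuracy}, \code{kappa}, \code{mapping}, \code{degenerate}.
#' @export
scoreClustering <- function(pred, truth) {
    ml <- matchLabels(pred, truth)
    evalConfusion(ml$matched, mapping = ml$mapping)
}

#' Accuracy and kappa of an already-matched confusion matrix
#'
#' @param matched square confusion matrix with matched classes on the
#'   diagonal.
#' @param mapping optional label mapping to carry through.
#' @return list as in \code{\link{scoreClustering}}.
#' @export
evalConfusion <- function(matched, mapping = NULL) {
    N <- sum(matched)
    stopifnot(N > 0)
    po <- sum(diag(matched)) / N
    pe <- sum(rowSums(matched) * colSums(matched)) / N^2
    if (1 - pe == 0) {
        kappa <- if (po == 1) 1 else 0
        degen <- TRUE
    } else {
        kappa <- (po - pe) / (1 - pe)
        degen <- FALSE
    }
    list(confusion = matched, accuracy = po, kappa = kappa,
         mapping = mapping, degenerate = degen)
}

#' Repeated stratified-subsampling robustness protocol
#'
#' For each class-ratio setting, cells are stratified-sampled \code{iters}
#' times (seeded); each subsample is taken through QC filtering,
#' winsorisation, CV selection and tree clustering to \code{targetK}
#' clusters, matched to truth with the Hungarian method, and the matched
#' confusion matrices are summed element-wise. Accuracy and kappa are
#' computed on each aggregate matrix (and per iteration for reference).
#'
#' Given ratio \code{r} over the truth classes, the per-class sample size
#' is \code{floor(base * r_c * fraction)} with
#' \code{base = min_c(n_c / r_c)}: the largest stratified sample at that
#' ratio, shrunk by \code{fraction} so iterations differ.
#'
#' @param nme assembled, unfiltered \linkS4class{NucMapExperiment}.
#' @param truth named vector of true class labels per cell.
#' @param proportions list of numeric class-ratio vectors (named by class
#'   or in \code{sort(unique(truth))} order).
#' @param iters iterations per proportion (default 100).
#' @param targetK number of clusters to cut (default: number of classes).
#' @param seed RNG seed.
#' @param fraction stratified sample shrinkage in (0, 1] (default 0.8).
#' @param maxCellException,maxMotifException,lower,upper,minCV pipeline
#'   parameters, as in the individual stages.
#' @return list of per-proportion results: \code{proportion},
#'   \code{aggregate} (summed matched confusion matrix), \code{accuracy},
#'   \code{kappa}, \code{perIteration} data.frame, \code{retainedFraction}.
#' @export
robustnessProtocol <- function(nme, truth, proportions, iters = 100L,
                               targetK = NULL, seed = 0L, fraction = 0.8,
                               maxCellException = 0.70,
                               maxMotifException = 0.90,
                               lower = 1, upper = 99, minCV = 0.5) {
    classes <- sort(unique(truth))
    if (is.null(targetK)) targetK <- length(classes)
    cellsByClass <- split(names(truth), truth)
    out <- vector("list", length(proportions))
    set.seed(seed)
    for (pi in seq_along(proportions)) {
        r <- proportions[[pi]]
        if (is.null(names(r))) names(r) <- classes
        stopifnot(setequal(names(r), classes), all(r > 0))
        base <- min(lengths(cellsByClass)[classes] / r[classes])
        nPer <- floor(base * r[classes] * fraction)
        if (any(nPer < 1L))
            stop("ratio exhausts a class: ",
                 paste(classes[nPer < 1L], collapse = ", "))
        d <- max(length(classes), targetK)
        agg <- matrix(0, d, d)
        rownames(agg) <- c(as.character(classes),
                           rep(NA_character_, d - length(classes)))
        perIter <- data.frame(iter = seq_len(iters), accuracy = NA_real_,
                              kappa = NA_real_, retained = NA_real_)
        for (it in seq_len(iters)) {
            pick <- unlist(lapply(classes, function(cl)
                sample(cellsByClass[[cl]], nPer[[cl]])))
            sub <- nme[, colnames(nme) %in% pick]
            subF <- filterMatrix(sub, maxCellException, maxMotifException)
            subF <- winsorizeMotifs(subF, lower, upper)
            subF <- cvSelect(subF, minCV)
            cr <- clusterCells(subF, method = "tree", k = targetK)
            cells <- names(clusterLabels(cr))
            sc <- scoreClustering(clusterLabels(cr), truth[cells])
            m <- sc$confusion
            ## align on truth rows; matched matrices share row order
            ri <- match(rownames(m), rownames(agg))
            ri[is.na(ri)] <- which(is.na(rownames(agg)))[
                seq_len(sum(is.na(ri)))]
            agg[ri, seq_len(ncol(m))] <- agg[ri, seq_len(ncol(m))] + m
            perIter$accuracy[it] <- sc$accuracy
            perIter$kappa[it] <- sc$kappa
            perIter$retained[it] <- length(cells) / length(pick)
        }
        ev <- evalConfusion(agg)
        out[[pi]] <- list(proportion = r, aggregate = agg,
                          accuracy = ev$accuracy, kappa = ev$kappa,
                          perIteration = perIter,
                          retainedFraction = mean(perIter$retained))
    }
    out
}

#' Write a robustness-protocol report
#'
#' One row per proportion: the ratio, iteration count, aggregate accuracy
#' and kappa, and mean retained fraction.
#'
#' @param results list from \code{\link{robustnessProtocol}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeEvalTSV <- function(results, path) {
    rows <- lapply(results, function(r) data.frame(
        proportion = paste(r$proportion, collapse = ":"),
        n_iters = nrow(r$perIteration),
        accuracy = r$accuracy, kappa = r$kappa,
        retained_fraction = r$retainedFraction))
    data.table::fwrite(do.call(rbind, rows), path, sep = "\t",
                       quote = FALSE)
    invisible(path)
}
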