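#' Principal component analysis of the scaled matrix
#'
#' Exact SVD (via the eigendecomposition of the gene-gene cross-product) of
#' the column-centered scaled matrix. Deterministic; the sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive. Components are ordered by non-increasing explained variance.
#'
#' @param scaled cells x genes matrix from [scaleGenes()].
#' @param nComponents number of components to keep (default 15).
#' @return list with `embedding` (cells x nComponents), `varExplained`
#'   (fraction of total variance per component) and `rotation`
#'   (genes x nComponents).
#' @export
runPCA <- function(scaled, nComponents = 15) {
    if (nComponents <= 0) stop("nComponents must be positive")
    if (nComponents > min(dim(scaled)))
        stop("nComponents exceeds min(cells, genes)")
    x <- sweep(scaled, 2L, colMeans(scaled), `-`)
    cp <- crossprod(x)
    eig <- eigen(cp, symmetric = TRUE)
    k <- nComponents
    rot <- eig$vectors[, seq_len(k), drop = FALSE]
    flip <- vapply(seq_len(k), function(j) {
        v <- rot[, j]
        sign(v[which.max(abs(v))])
    }, numeric(1))
    rot <- sweep(rot, 2L, flip, `*`)
    emb <- x %*% rot
    ev <- pmax(eig$values, 0)
    dimnames(rot) <- list(colnames(scaled), paste0("PC", seq_len(k)))
    dimnames(emb) <- list(rownames(scaled), paste0("PC", seq_len(k)))
    list(embedding = emb, varExplained = ev[seq_len(k)] / sum(ev),
         rotation = rot)
}

# k nearest neighbors (including the cell itself) by Euclidean distance,
# computed in blocks so no full n x n distance matrix is materialized.
.knn <- function(emb, k, blockSize = 1024L) {
    n <- nrow(emb)
    sq <- rowSums(emb^2)
    idx <- matrix(0L, n, k)
    for (from in seq(1L, n, by = blockSize)) {
        to <- min(from + blockSize - 1L, n)
        cross <- emb %*% t(emb[from:to, , drop = FALSE])
        d2 <- sq - 2 * cross + rep(sq[from:to], each = n)
        for (j in seq_len(to - from + 1L)) {
            d <- d2[, j]
            d[from + j - 1L] <- -Inf  # the cell is always its own neighbor
            idx[from + j - 1L, ] <- order(d)[seq_len(k)]
        }
    }
    idx
}

#' Shared nearest-neighbor graph clustering (Louvain)
#'
#' Builds a k-nearest-neighbor graph on Euclidean distances in the
#' embedding (each cell counts as its own neighbor), weights each edge by
#' the Jaccard overlap of the two cells' neighbor sets (edges with overlap
#' below `pruneSNN` are dropped), and maximizes resolution-scaled
#' modularity with the Louvain algorithm. Deterministic for a fixed seed.
#' Cluster labels are contiguous integers from 0, ordered by decreasing
#' cluster size.
#'
#' @param embedding cells x d matrix, or the list returned by [runPCA()].
#' @param kNeighbors neighborhood size (default 20; must be < n cells).
#' @param resolution modularity resolution (default 0.3; smaller gives
#'   fewer, larger clusters, with a single cluster in the limit).
#' @param seed RNG seed for the Louvain local-moving order.
#' @param pruneSNN Jaccard cutoff below which SNN edges are removed
#'   (default 1/15).
#' @return list with `labels` (0-based integer per cell), `resolution`, and
#'   `modularity` (resolution-scaled, as achieved on the SNN graph).
#' @export
clusterGraph <- function(embedding, kNeighbors = 20, resolution = 0.3,
                         seed = 0, pruneSNN = 1 / 15) {
    if (is.list(embedding)) embedding <- embedding$embedding
    n <- nrow(embedding)
    if (n < 3) stop("need at least 3 cells to cluster")
    k <- as.integer(min(kNeighbors, n - 1L))
    nn <- .knn(embedding, k)
    adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                                x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(adj)
    jac <- shared
    jac@x <- jac@x / (2 * k - jac@x)
    jac@x[jac@x < pruneSNN] <- 0
    jac <- Matrix::drop0(jac)
    Matrix::diag(jac) <- 0
    jac <- Matrix::drop0(jac)
    g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                             weighted = TRUE)
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    memb <- igraph::membership(cl)
    sizes <- table(memb)
    newId <- setNames(seq_along(sizes) - 1L,
                      names(sort(sizes, decreasing = TRUE)))
    labels <- as.integer(newId[as.character(memb)])
    mod <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                              resolution = resolution)
    list(labels = labels, resolution = resolution, modularity = mod)
}

# Vectorized two-sided Wilcoxon rank-sum tests of one cell group against the
# rest, one test per gene, using the normal approximation with tie and
# continuity correction (the same approximation as stats::wilcox.test with
# exact = FALSE). `ranks` are per-gene ranks over all cells and `tieTerm`
# the per-gene sum of (t^3 - t) over tied groups.
.rankSumP <- function(ranks, tieTerm, inGroup) {
    n <- nrow(ranks)
    n1 <- sum(inGroup)
    n2 <- n - n1
    r1 <- colSums(ranks[inGroup, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    muU <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- u - muU
    corr <- sign(z) * 0.5
    sigma <- sqrt(pmax(sigma2, 0))
    z <- ifelse(sigma > 0, (z - corr) / sigma, 0)
    pmin(1, 2 * pnorm(-abs(z)))
}

.tieTerm <- function(x) {
    t <- rle(sort(x))$lengths
    sum(t^3 - t)
}

#' Cluster marker genes by Wilcoxon rank-sum test
#'
#' For every cluster against all other cells: genes are pre-filtered to
#' those detected in at least `minPct` of the cluster's cells and with an
#' absolute log fold-change (natural log of the cluster-vs-rest ratio of
#' mean `expm1` log-normalized expression, pseudocount 1 in numerator and
#' denominator) of at least `minLogFC`; the surviving genes are tested with
#' a two-sided Wilcoxon rank-sum test (normal approximation with tie and
#' continuity correction) and Bonferroni-adjusted by the total number of
#' genes in the data. The reported table is additionally restricted to
#' `adjusted_p < pCutoff` and `|log2FC| > log2fcCutoff`, applied after the
#' pre-filter exactly as in the two-stage convention.
#'
#' Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param cohort a [PCPGCohort-class] with `"logcounts"`.
#' @param clusters integer/character cluster label per cell.
#' @param minPct minimum within-cluster detection fraction (default 0.25).
#' @param minLogFC pre-filter on |ln fold-change| (default 0.25).
#' @param pCutoff adjusted p-value cutoff for the final table (default 0.05).
#' @param log2fcCutoff |log2 fold-change| cutoff for the final table
#'   (default 1.2).
#' @return data.frame with columns `cluster`, `gene`, `log2_fold_change`,
#'   `pct_in`, `pct_out`, `p_value`, `adjusted_p`.
#' @export
findMarkers <- function(cohort, clusters, minPct = 0.25, minLogFC = 0.25,
                        pCutoff = 0.05, log2fcCutoff = 1.2) {
    .assertCohort(cohort)
    if (length(unique(clusters)) < 2) stop("need at least 2 clusters")
    x <- .cellsByGenes(cohort, "logcounts")  # cells x genes
    nGenesTotal <- ncol(x)
    ranks <- .columnRanks(x)
    tieTerm <- apply(x, 2L, .tieTerm)
    detected <- x > 0
    em <- expm1(x)
    out <- list()
    for (cl in sort(unique(clusters))) {
        inGroup <- clusters == cl
        if (sum(inGroup) < 3) {
            warning("cluster ", cl, " has fewer than 3 cells; skipped")
            next
        }
        pctIn <- colMeans(detected[inGroup, , drop = FALSE])
        pctOut <- colMeans(detected[!inGroup, , drop = FALSE])
        mIn <- colMeans(em[inGroup, , drop = FALSE])
        mOut <- colMeans(em[!inGroup, , drop = FALSE])
        lnFC <- log(mIn + 1) - log(mOut + 1)
        test <- pctIn >= minPct & abs(lnFC) >= minLogFC
        if (!any(test)) next
        p <- .rankSumP(ranks[, test, drop = FALSE], tieTerm[test], inGroup)
        padj <- pmin(1, p * nGenesTotal)
        log2fc <- lnFC[test] / log(2)
        keep <- padj < pCutoff & abs(log2fc) > log2fcCutoff
        if (!any(keep)) next
        out[[length(out) + 1L]] <- data.frame(
            cluster = cl, gene = colnames(x)[test][keep],
            log2_fold_change = log2fc[keep],
            pct_in = pctIn[test][keep], pct_out = pctOut[test][keep],
            p_value = p[keep], adjusted_p = padj[keep],
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(cluster = integer(), gene = character(),
                          log2_fold_change = numeric(), pct_in = numeric(),
                          pct_out = numeric(), p_value = numeric(),
                          adjusted_p = numeric()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Marker-panel cell-type annotation
#'
#' Per cluster, computes the mean log-normalized expression of each marker
#' panel and assigns the argmax panel. Panel genes missing from the matrix
#' are dropped with a warning (error if a whole panel is absent). Exact
#' ties are broken by panel order and flagged ambiguous.
#'
#' @param cohort a [PCPGCohort-class] with `"logcounts"`.
#' @param clusters cluster label per cell.
#' @param panels named list of marker gene vectors, one per cell type.
#' @return list with `clusters` (data.frame: `cluster`, `type`, `score`,
#'   `margin`, `ambiguous`) and `cellType` (character per cell).
#' @export
annotateCellTypes <- function(cohort, clusters, panels) {
    .assertCohort(cohort)
    if (!length(panels) || any(!nzchar(names(panels))))
        stop("panels must be a non-empty named list")
    x <- assay(cohort, "logcounts")
    panels <- lapply(setNames(names(panels), names(panels)), function(ty) {
        genes <- panels[[ty]]
        miss <- setdiff(genes, rownames(x))
        if (length(miss) == length(genes))
            stop("all marker genes of panel '", ty, "' are missing")
        if (length(miss))
            warning("panel '", ty, "': dropping missing gene(s) ",
                    paste(miss, collapse = ", "))
        intersect(genes, rownames(x))
    })
    cls <- sort(unique(clusters))
    scores <- vapply(panels, function(genes) {
        panelMean <- Matrix::colMeans(x[genes, , drop = FALSE])
        vapply(cls, function(cl) mean(panelMean[clusters == cl]), numeric(1))
    }, numeric(length(cls)))
    scores <- matrix(scores, nrow = length(cls),
                     dimnames = list(NULL, names(panels)))
    best <- apply(scores, 1L, which.max)  # ties -> first (panel order)
    margin <- vapply(seq_along(cls), function(i) {
        s <- sort(scores[i, ], decreasing = TRUE)
        s[1] - s[2]
    }, numeric(1))
    df <- data.frame(cluster = cls, type = names(panels)[best],
                     score = scores[cbind(seq_along(cls), best)],
                     margin = margin, ambiguous = margin == 0,
                     stringsAsFactors = FALSE)
    cellType <- df$type[match(clusters, df$cluster)]
    list(clusters = df, cellType = cellType)
}

#' Cell-type composition summary
#'
#' Fractions of each annotated cell type over the whole dataset and within
#' each sample. Fractions sum to 1 within each grouping.
#'
#' @param cellTypes character per cell.
#' @param sampleIds sample id per cell.
#' @return data.frame with columns `scope` (`"overall"` or a sample id),
#'   `type`, `n`, `fraction`.
#' @export
compositionSummary <- function(cellTypes, sampleIds) {
    if (length(cellTypes) != length(sampleIds))
        stop("cellTypes and sampleIds must be aligned")
    one <- function(scope, idx) {
        tab <- table(cellTypes[idx])
        data.frame(scope = scope, type = names(tab), n = as.integer(tab),
                   fraction = as.numeric(tab) / sum(tab),
                   stringsAsFactors = FALSE)
    }
    out <- rbind(one("overall", seq_along(cellTypes)),
                 do.call(rbind, lapply(sort(unique(sampleIds)), function(s)
                     one(s, which(sampleIds == s)))))
    rownames(out) <- NULL
    out
}
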