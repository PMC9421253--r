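#' Prepare the per-sample NMF input matrix
#'
#' Two documented conventions for the non-negative input of the per-sample
#' factorization: `"centered"` (default in the pipeline) subtracts each
#' gene's mean across the sample's cells and clips negative values to zero,
#' the usual preparation for intra-tumor program discovery — it removes all
#' within-sample-constant structure (expression baseline, patient-private
#' shifts, dosage segments), so factors capture cell-to-cell variation
#' only; `"lognorm"` passes the log-normalized values through unchanged, in
#' which case factors also absorb the sample's baseline profile.
#'
#' @param x genes x cells log-normalized matrix of one sample's tumor
#'   cells (restricted to the cohort's variable genes).
#' @param method `"centered"` or `"lognorm"`.
#' @return non-negative genes x cells matrix for [nmfFactorize()].
#' @export
prepareNMFInput <- function(x, method = c("centered", "lognorm")) {
    method <- match.arg(method)
    x <- as.matrix(x)
    if (method == "centered") {
        x <- x - rowMeans(x)
        x[x < 0] <- 0
    }
    x
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative genes x cells matrix `x` (the log-normalized
#' tumor-cell submatrix of one sample, restricted to the cohort's variable
#' genes) as `x ~ W %*% H` with `W >= 0` (genes x k) and `H >= 0`
#' (k x cells), minimizing the Frobenius loss with Lee-Seung multiplicative
#' updates from a seeded uniform-random initialization scaled by the matrix
#' mean. Iteration stops when the relative objective decrease falls below
#' `tol` or after `maxIter` iterations; the per-iteration objective trace is
#' retained (non-increasing by construction). On return the columns of `W`
#' are scaled to unit L2 norm with the inverse scaling applied to the rows
#' of `H`.
#'
#' @param x non-negative genes x cells matrix with dimnames.
#' @param k number of factors (default 28); must be < min(dim(x)).
#' @param seed RNG seed for the initialization.
#' @param maxIter maximum iterations (default 500).
#' @param tol relative objective-change stopping tolerance (default 1e-5).
#' @param sampleId label stored with the result.
#' @return an [NMFResult-class].
#' @export
nmfFactorize <- function(x, k = 28, seed = 0, maxIter = 500, tol = 1e-5,
                         sampleId = "sample") {
    x <- as.matrix(x)
    if (any(x < 0)) stop("input matrix must be non-negative")
    if (all(x == 0)) stop("input matrix is all zero")
    k <- as.integer(k)
    if (k >= min(dim(x))) stop("k must be < min(genes, cells)")
    eps <- 1e-10
    set.seed(as.integer(seed))
    scale0 <- sqrt(mean(x) / k)
    W <- matrix(runif(nrow(x) * k), nrow(x), k) * scale0
    H <- matrix(runif(k * ncol(x)), k, ncol(x)) * scale0
    normX2 <- sum(x^2)
    objective <- numeric(0)
    objAt <- function(W, H) {
        WtX <- crossprod(W, x)
        normX2 - 2 * sum(WtX * H) + sum(crossprod(W) * tcrossprod(H))
    }
    prev <- objAt(W, H)
    objective <- prev
    for (it in seq_len(maxIter)) {
        WtX <- crossprod(W, x)
        H <- H * WtX / (crossprod(W) %*% H + eps)
        HHt <- tcrossprod(H)
        W <- W * (x %*% t(H)) / (W %*% HHt + eps)
        cur <- objAt(W, H)
        objective <- c(objective, cur)
        if (prev - cur < tol * prev) break
        prev <- cur
    }
    nrm <- sqrt(colSums(W^2))
    nrm[nrm == 0] <- 1
    W <- sweep(W, 2L, nrm, `/`)
    H <- sweep(H, 1L, nrm, `*`)
    dimnames(W) <- list(rownames(x), paste0("factor", seq_len(k)))
    dimnames(H) <- list(paste0("factor", seq_len(k)), colnames(x))
    methods::new("NMFResult", sampleId = sampleId, W = W, H = H, k = k,
                 objective = objective, seed = as.integer(seed))
}

#' Extract top-gene programs from NMF factors
#'
#' Per factor, the `topN` genes with the highest loading in the
#' corresponding column of `W` (ties broken by gene id); genes with zero or
#' negative loading are never included, so a factor with fewer than `topN`
#' positive loadings yields a shorter program (with a warning).
#'
#' @param results an [NMFResult-class] or a list of them (one per sample).
#' @param topN program length (default 50).
#' @return a [ProgramSet-class]; program ids are `"<sample>.f<factor>"`.
#' @export
extractPrograms <- function(results, topN = 50) {
    if (methods::is(results, "NMFResult")) results <- list(results)
    topN <- as.integer(topN)
    rows <- list()
    for (res in results) {
        W <- res@W
        for (f in seq_len(res@k)) {
            load <- W[, f]
            pos <- which(load > 0)
            if (length(pos) < topN)
                warning("sample ", res@sampleId, " factor ", f, " has only ",
                        length(pos), " positive loadings")
            ord <- pos[order(-load[pos], rownames(W)[pos])]
            take <- head(ord, topN)
            if (!length(take)) next
            rows[[length(rows) + 1L]] <- data.frame(
                program_id = sprintf("%s.f%02d", res@sampleId, f),
                sample_id = res@sampleId, factor = f,
                rank = seq_along(take), gene = rownames(W)[take],
                loading = unname(load[take]), stringsAsFactors = FALSE)
        }
    }
    methods::new("ProgramSet", programs = do.call(rbind, rows), topN = topN)
}

# Equal-frequency expression bins over genes, computed once per matrix.
.expressionBins <- function(nm, nBins) {
    avg <- colMeans(nm)
    breaks <- unique(quantile(avg, probs = seq(0, 1, length.out = nBins + 1)))
    cut(avg, breaks = breaks, include.lowest = TRUE)
}

#' Module score with expression-binned control genes
#'
#' Scores each cell for a gene set: all genes are binned into `nBins`
#' equal-frequency bins of mean expression; for every gene of the set,
#' `nCtrl` control genes are sampled (with replacement) from its bin; the
#' score is the mean expression of the set genes minus the mean expression
#' of the pooled control genes. Centered near zero for a random gene set,
#' positive when the set is coherently active in a cell.
#'
#' @param nm cells x genes normalized (log) expression matrix.
#' @param geneSet character vector; genes absent from `nm` are dropped
#'   (error if none remain).
#' @param nBins expression bins (default 25).
#' @param nCtrl control genes sampled per set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @param bins optional precomputed factor from an earlier call (one entry
#'   per column of `nm`), so many scores share one binning.
#' @return numeric score per cell (named by cell id).
#' @export
moduleScore <- function(nm, geneSet, nBins = 25, nCtrl = 100, seed = 0,
                        bins = NULL) {
    geneSet <- intersect(geneSet, colnames(nm))
    if (!length(geneSet)) stop("gene set has no genes in the matrix")
    if (is.null(bins)) bins <- .expressionBins(nm, nBins)
    set.seed(as.integer(seed))
    sampled <- unlist(lapply(geneSet, function(g) {
        pool <- which(bins == bins[match(g, colnames(nm))])
        pool[sample.int(length(pool), nCtrl, replace = TRUE)]
    }))
    ctrlCounts <- tabulate(sampled, nbins = ncol(nm))
    ctrlMean <- as.vector(nm %*% ctrlCounts) / length(sampled)
    setMean <- rowMeans(nm[, geneSet, drop = FALSE])
    setNames(setMean - ctrlMean, rownames(nm))
}

#' Score all programs across all tumor cells
#'
#' [moduleScore()] for every program of a [ProgramSet-class] on a shared
#' expression binning (computed once). Control sampling for each program
#' uses a seed derived from `seed` and a content hash of the program's gene
#' set, so adding, removing or reordering programs never changes any other
#' column, and duplicated programs receive identical columns.
#'
#' @param nm cells x genes normalized expression matrix (all tumor cells).
#' @param programSet a [ProgramSet-class].
#' @param nBins,nCtrl as in [moduleScore()].
#' @param seed master seed for the per-program control draws.
#' @return cells x programs score matrix (columns in program order).
#' @export
scoreAllPrograms <- function(nm, programSet, nBins = 25, nCtrl = 100,
                             seed = 0) {
    tab <- programs(programSet)
    ids <- unique(tab$program_id)
    if (!length(ids)) stop("empty program set")
    bins <- .expressionBins(nm, nBins)
    scores <- vapply(seq_along(ids), function(i) {
        genes <- tab$gene[tab$program_id == ids[i]]
        h <- sum(utf8ToInt(paste(sort(genes), collapse = ""))) %% 1000003L
        moduleScore(nm, genes, nBins = nBins, nCtrl = nCtrl,
                    seed = .deriveSeed(seed, 1000L + h), bins = bins)
    }, numeric(nrow(nm)))
    scores <- matrix(scores, nrow = nrow(nm),
                     dimnames = list(rownames(nm), ids))
    scores
}

# Mean silhouette width of a partition on a precomputed distance matrix;
# singleton clusters contribute 0.
.meanSilhouette <- function(d, labels) {
    n <- nrow(d)
    cls <- unique(labels)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- labels == labels[i]
        nOwn <- sum(own) - 1L
        if (nOwn == 0L) { s[i] <- 0; next }
        a <- sum(d[i, own]) / nOwn
        b <- min(vapply(setdiff(cls, labels[i]), function(cl)
            mean(d[i, labels == cl]), numeric(1)))
        s[i] <- (b - a) / max(a, b)
    }
    mean(s)
}

# Cross-sample recurrence of programs: a program is recurrent when its
# top-gene set shares at least `overlap` genes with a program extracted
# from a different sample. Computed from a sparse gene x program incidence.
.recurrentPrograms <- function(programSet, overlap) {
    tab <- programs(programSet)
    ids <- unique(tab$program_id)
    genes <- unique(tab$gene)
    inc <- Matrix::sparseMatrix(
        i = match(tab$gene, genes), j = match(tab$program_id, ids),
        x = 1, dims = c(length(genes), length(ids)))
    ov <- as.matrix(Matrix::crossprod(inc))
    samp <- tab$sample_id[match(ids, tab$program_id)]
    sameSample <- outer(samp, samp, `==`)
    ov[sameSample] <- 0
    setNames(apply(ov, 1L, max) >= overlap, ids)
}

#' Cluster programs into metaprograms
#'
#' Computes the Pearson correlation between program score columns, converts
#' it to the distance `1 - r`, and clusters with Ward linkage. The tree is
#' cut either at `nMeta` clusters or, with `nMeta = "auto"`, at the cut
#' among `kRange` with the largest mean silhouette width (ties to the
#' smallest K). Each metaprogram's genes are ranked by their frequency of
#' presence among its recurrent constituent programs, ties broken by mean
#' within-program loading rank, then gene id.
#'
#' Metaprograms are, by definition, expression programs shared across
#' tumors, so the dendrogram and the cut are computed on the recurrent
#' programs only: those whose top-gene set shares at least
#' `recurrentOverlap` genes with a program extracted from a different
#' sample. Sample-private and noise factors (which recur nowhere) would
#' otherwise accumulate in diffuse clusters that distort the cut; they are
#' instead attached afterwards, each to the metaprogram whose defining
#' programs its score column correlates with most, so every program still
#' receives exactly one assignment. Set `recurrentOverlap = 0` to cluster
#' all programs directly.
#'
#' Programs with constant score columns have undefined correlations and are
#' dropped with a warning.
#'
#' @param scoreMatrix cells x programs matrix from [scoreAllPrograms()].
#' @param programSet the matching [ProgramSet-class].
#' @param nMeta number of metaprograms, or `"auto"` (default).
#' @param kRange candidate cluster counts for the auto cut (default 2:15).
#' @param recurrentOverlap minimum cross-sample top-gene overlap (in genes)
#'   for a program to help define the clusters (default 20; 0 disables).
#' @return a [MetaprogramSet-class] (cell scores empty until
#'   [scoreMetaprograms()] is run).
#' @export
clusterMetaprograms <- function(scoreMatrix, programSet, nMeta = "auto",
                                kRange = 2:15, recurrentOverlap = 20) {
    if (ncol(scoreMatrix) < 2) stop("need at least 2 programs")
    sds <- apply(scoreMatrix, 2L, sd)
    if (any(sds == 0)) {
        warning("dropping constant-score program(s): ",
                paste(colnames(scoreMatrix)[sds == 0], collapse = ", "))
        scoreMatrix <- scoreMatrix[, sds > 0, drop = FALSE]
    }
    ids <- colnames(scoreMatrix)
    recurrent <- if (recurrentOverlap > 0)
        .recurrentPrograms(programSet, recurrentOverlap)[ids]
    else setNames(rep(TRUE, length(ids)), ids)
    if (sum(recurrent) < 2) {
        warning("fewer than 2 recurrent programs; clustering all programs")
        recurrent[] <- TRUE
    }
    r <- cor(scoreMatrix)
    core <- ids[recurrent]
    d <- 1 - r[core, core, drop = FALSE]
    hc <- hclust(stats::as.dist(d), method = "ward.D2")
    silTab <- data.frame(k = integer(), silhouette = numeric())
    if (identical(nMeta, "auto")) {
        kRange <- kRange[kRange < length(core)]
        sil <- vapply(kRange, function(k)
            .meanSilhouette(d, cutree(hc, k = k)), numeric(1))
        silTab <- data.frame(k = kRange, silhouette = sil)
        nMeta <- kRange[which.max(sil)]
    }
    nMeta <- as.integer(nMeta)
    coreAssign <- cutree(hc, k = nMeta)
    assignment <- setNames(integer(length(ids)), ids)
    assignment[core] <- coreAssign
    for (p in ids[!recurrent]) {
        meanR <- vapply(seq_len(nMeta), function(m)
            mean(r[p, core[coreAssign == m]]), numeric(1))
        assignment[p] <- which.max(meanR)
    }
    tab <- programs(programSet)
    geneRows <- do.call(rbind, lapply(seq_len(nMeta), function(m) {
        members <- core[coreAssign == m]
        sub <- tab[tab$program_id %in% members, , drop = FALSE]
        freq <- table(sub$gene) / length(members)
        meanRank <- tapply(sub$rank, sub$gene, mean)
        genes <- names(freq)
        ord <- order(-as.numeric(freq), meanRank[genes], genes)
        data.frame(metaprogram = m, rank = seq_along(ord),
                   gene = genes[ord],
                   frequency = pmin(1, as.numeric(freq)[ord]),
                   mean_loading_rank = as.numeric(meanRank[genes])[ord],
                   stringsAsFactors = FALSE)
    }))
    methods::new("MetaprogramSet", assignment = assignment,
                 nMeta = nMeta, genes = geneRows,
                 cellScores = matrix(numeric(0), 0, 0),
                 silhouette = silTab, recurrent = recurrent)
}

#' Score cells for each metaprogram
#'
#' [moduleScore()] on each metaprogram's top `topN` frequency-ranked genes,
#' sharing one expression binning. Fills the `cellScores` slot.
#'
#' @param nm cells x genes normalized expression matrix.
#' @param metaprograms a [MetaprogramSet-class].
#' @param topN genes per metaprogram (default 50).
#' @param nBins,nCtrl,seed as in [scoreAllPrograms()].
#' @return the [MetaprogramSet-class] with `cellScores` set
#'   (cells x metaprograms, columns `M1`, `M2`, ...).
#' @export
scoreMetaprograms <- function(nm, metaprograms, topN = 50, nBins = 25,
                              nCtrl = 100, seed = 0) {
    gtab <- metaprogramGenes(metaprograms)
    bins <- .expressionBins(nm, nBins)
    ms <- vapply(seq_len(metaprograms@nMeta), function(m) {
        genes <- head(gtab$gene[gtab$metaprogram == m], topN)
        moduleScore(nm, genes, nBins = nBins, nCtrl = nCtrl,
                    seed = .deriveSeed(seed, 2000L + m), bins = bins)
    }, numeric(nrow(nm)))
    ms <- matrix(ms, nrow = nrow(nm),
                 dimnames = list(rownames(nm),
                                 paste0("M", seq_len(metaprograms@nMeta))))
    metaprograms@cellScores <- ms
    methods::validObject(metaprograms)
    metaprograms
}

#' Compare metaprogram scores between mutation groups
#'
#' Per metaprogram, a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie and continuity correction) of the per-cell scores
#' between the two mutation groups, plus the group means.
#'
#' @param metaScores cells x metaprograms score matrix.
#' @param groups mutation group per cell; exactly two groups, each with at
#'   least 3 cells.
#' @return data.frame with columns `metaprogram`, `mean_<group1>`,
#'   `mean_<group2>`, `statistic`, `p_value`.
#' @export
compareGroups <- function(metaScores, groups) {
    groups <- as.character(groups)
    lev <- sort(unique(groups))
    if (length(lev) != 2) stop("need exactly two groups")
    if (any(table(groups) < 3)) stop("each group needs at least 3 cells")
    res <- do.call(rbind, lapply(colnames(metaScores), function(m) {
        sc <- metaScores[, m]
        wt <- wilcox.test(sc[groups == lev[1]], sc[groups == lev[2]],
                          exact = FALSE, correct = TRUE)
        data.frame(metaprogram = m,
                   mean1 = mean(sc[groups == lev[1]]),
                   mean2 = mean(sc[groups == lev[2]]),
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value, stringsAsFactors = FALSE)
    }))
    names(res)[2:3] <- paste0("mean_", lev)
    rownames(res) <- NULL
    res
}
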