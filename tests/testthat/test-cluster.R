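test_that("PCA captures a planted rank-1 structure and is equivariant", {
    set.seed(5)
    u <- rnorm(200); v <- rnorm(80)
    x <- outer(u, v) + matrix(rnorm(200 * 80, sd = 1e-3), 200, 80)
    dimnames(x) <- list(sprintf("c%03d", 1:200), sprintf("g%02d", 1:80))
    p <- runPCA(x, nComponents = 5)
    expect_gte(p$varExplained[1], 0.99)
    expect_true(all(diff(p$varExplained) <= 1e-12))
    # permuting cells permutes embedding rows identically
    perm <- sample(200)
    p2 <- runPCA(x[perm, ], nComponents = 5)
    expect_equal(p2$embedding, p$embedding[perm, ], tolerance = 1e-6)
    # truncated reconstruction achieves the optimal (Eckart-Young) error
    xc <- sweep(x, 2, colMeans(x))
    recon <- p$embedding %*% t(p$rotation)
    ev <- eigen(crossprod(xc), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum((xc - recon)^2), sum(ev[-(1:5)]), tolerance = 1e-6)
    expect_error(runPCA(x, 0), "positive")
})

test_that("graph clustering recovers separated blobs exactly", {
    set.seed(9)
    centers <- rbind(c(0, 0), c(30, 0), c(0, 30))
    lab <- rep(1:3, each = 60)
    emb <- centers[lab, ] + matrix(rnorm(180 * 2, sd = 0.5), 180, 2)
    cl <- clusterGraph(emb, kNeighbors = 15, resolution = 0.3, seed = 1)
    expect_identical(sort(unique(cl$labels)), 0:2)
    expect_equal(ari(cl$labels, lab), 1)
    expect_error(clusterGraph(emb[1:2, ]), "at least 3")
})

test_that("the resolution -> 0 limit yields a single cluster", {
    set.seed(10)
    emb <- matrix(rnorm(100 * 2), 100, 2)
    cl <- clusterGraph(emb, kNeighbors = 10, resolution = 1e-9, seed = 1)
    expect_identical(unique(cl$labels), 0L)
})

test_that("duplicated points always share a cluster", {
    set.seed(11)
    emb <- matrix(rnorm(60 * 3), 60, 3)
    dup <- rbind(emb, emb)
    cl <- clusterGraph(dup, kNeighbors = 10, seed = 2)
    expect_identical(cl$labels[1:60], cl$labels[61:120])
})

test_that("achieved modularity beats trivial and random partitions", {
    set.seed(12)
    centers <- rbind(c(0, 0), c(20, 0), c(0, 20), c(20, 20))
    lab <- rep(1:4, each = 40)
    emb <- centers[lab, ] + matrix(rnorm(160 * 2, sd = 0.8), 160, 2)
    cl <- clusterGraph(emb, kNeighbors = 12, resolution = 0.5, seed = 3)
    # rebuild the same SNN graph to evaluate alternative partitions
    n <- nrow(emb)
    nn <- pcpgHet:::.knn(emb, 12L)
    adj <- Matrix::sparseMatrix(i = rep(seq_len(n), 12), j = as.vector(nn),
                                x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(adj)
    jac <- shared; jac@x <- jac@x / (24 - jac@x)
    jac@x[jac@x < 1 / 15] <- 0
    jac <- Matrix::drop0(jac); Matrix::diag(jac) <- 0
    g <- igraph::graph_from_adjacency_matrix(Matrix::drop0(jac),
                                             mode = "undirected",
                                             weighted = TRUE)
    w <- igraph::E(g)$weight
    modOf <- function(memb) igraph::modularity(g, memb + 1L, weights = w,
                                               resolution = 0.5)
    achieved <- modOf(cl$labels)
    expect_gte(achieved, modOf(rep(0L, n)))
    for (s in 1:5) {
        set.seed(s)
        expect_gte(achieved, modOf(sample(0:3, n, replace = TRUE)))
    }
})

test_that("marker detection reports exclusive genes and skips null genes", {
    set.seed(13)
    n1 <- 30; n2 <- 30
    m <- matrix(rpois((n1 + n2) * 50, 2), 50, n1 + n2,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("c%02d", 1:(n1 + n2))))
    m["g01", ] <- c(rep(20L, n1), rep(0L, n2))  # exclusive to cluster 0
    co <- normalizeLog(toyCohort(m))
    clusters <- rep(c(0L, 1L), c(n1, n2))
    mk <- findMarkers(co, clusters)
    hit <- mk[mk$gene == "g01" & mk$cluster == 0, ]
    expect_identical(nrow(hit), 1L)
    expect_equal(hit$pct_in, 1)
    expect_equal(hit$pct_out, 0)
    expect_lt(hit$adjusted_p, 0.05)
    # identically distributed genes are not reported
    expect_false(any(mk$gene == "g02"))
})

test_that("rank-sum p-values match the exhaustive permutation oracle", {
    # At 20 cells the normal approximation tracks the exact permutation law
    # within 0.01 everywhere; at 12 cells the approximation itself deviates
    # by up to ~0.016 even without ties, so 0.02 is the attainable bound.
    set.seed(14)
    combs20 <- combsFor(20, 10)
    for (rep in 1:6) {
        x <- rlnorm(20, mean = rep(c(0, rep * 0.2), each = 10))
        inGroup <- rep(c(TRUE, FALSE), each = 10)
        p <- pcpgHet:::.rankSumP(matrix(rank(x), ncol = 1),
                                 pcpgHet:::.tieTerm(x), inGroup)
        expect_lt(abs(p - exactRankSumP(x, inGroup, combs20)), 0.01)
    }
    combs12 <- combsFor(12, 6)
    for (rep in 1:8) {
        x <- rlnorm(12, mean = rep(c(0, rep * 0.15), each = 6))
        inGroup <- rep(c(TRUE, FALSE), each = 6)
        p <- pcpgHet:::.rankSumP(matrix(rank(x), ncol = 1),
                                 pcpgHet:::.tieTerm(x), inGroup)
        expect_lt(abs(p - exactRankSumP(x, inGroup, combs12)), 0.02)
    }
})

test_that("rank-sum approximation agrees with stats::wilcox.test", {
    set.seed(15)
    x <- c(rpois(40, 2), rpois(35, 4))
    inGroup <- rep(c(TRUE, FALSE), c(40, 35))
    ranks <- matrix(rank(x), ncol = 1)
    p <- pcpgHet:::.rankSumP(ranks, pcpgHet:::.tieTerm(x), inGroup)
    pRef <- suppressWarnings(
        wilcox.test(x[inGroup], x[!inGroup], exact = FALSE,
                    correct = TRUE)$p.value)
    expect_equal(unname(p), pRef, tolerance = 1e-9)
})

test_that("label-permuted data yields almost no significant markers", {
    co <- smallCohort()
    set.seed(16)
    fake <- sample(rep(0:1, length.out = ncol(co)))
    mk <- findMarkers(co, fake)
    expect_lte(nrow(mk), ceiling(0.05 * nrow(co)))
})

test_that("annotation assigns panels, breaks ties by order, flags them", {
    m <- matrix(0L, 4, 6, dimnames = list(c("a1", "a2", "b1", "b2"),
                                          sprintf("c%d", 1:6)))
    m[c("a1", "a2"), 1:3] <- 5L
    m[c("b1", "b2"), 4:6] <- 5L
    co <- normalizeLog(toyCohort(m + 1L))
    clusters <- rep(c(0L, 1L), each = 3)
    ann <- annotateCellTypes(co, clusters,
                             list(A = c("a1", "a2"), B = c("b1", "b2")))
    expect_identical(ann$clusters$type, c("A", "B"))
    expect_false(any(ann$clusters$ambiguous))
    # exact tie: both panels read the same genes
    tie <- annotateCellTypes(co, clusters,
                             list(P = c("a1", "b1"), Q = c("a1", "b1")))
    expect_identical(tie$clusters$type, c("P", "P"))
    expect_true(all(tie$clusters$ambiguous))
    expect_warning(
        annotateCellTypes(co, clusters, list(A = c("a1", "zz"), B = "b1")),
        "missing")
    expect_error(
        annotateCellTypes(co, clusters, list(A = c("zz", "yy"), B = "b1")),
        "all marker genes")
})

test_that("the full stage recovers planted cell types on a small cohort", {
    co <- smallCohort()
    cfg <- smallConfig()
    hv <- selectHVG(co, n = 1000)
    sc <- scaleGenes(co, hv$gene[hv$selected])
    cl <- clusterGraph(runPCA(sc, 15), seed = 4)
    ann <- annotateCellTypes(co, cl$labels, cfg@markerPanels)
    expect_gte(ari(ann$cellType, colData(co)$true_cell_type), 0.9)
})

test_that("composition fractions are conserved across groupings", {
    types <- c("a", "a", "b", "b", "b", "a")
    samp <- c("s1", "s1", "s1", "s2", "s2", "s2")
    comp <- compositionSummary(types, samp)
    overall <- comp[comp$scope == "overall", ]
    expect_equal(sum(overall$fraction), 1)
    perSample <- comp[comp$scope != "overall", ]
    for (ty in unique(types)) {
        weighted <- sum(perSample$n[perSample$type == ty]) / length(types)
        expect_equal(weighted, overall$fraction[overall$type == ty])
    }
    one <- compositionSummary(rep("x", 5), rep("s", 5))
    expect_equal(one$fraction[one$scope == "overall"], 1)
})
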