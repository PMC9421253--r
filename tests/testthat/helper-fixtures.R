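# Shared fixtures and small oracles. Everything is generated in code; the
# expensive cohorts are memoised so several test files can share one build.

.cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
    if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
    get(key, envir = .cache)
}

# Small default-structure cohort for module-level tests (full structure,
# reduced cell count).
smallCohort <- function() {
    memo("smallCohort", function() {
        cfg <- defaultCohortConfig(cellsPerSample = 150)
        normalizeLog(filterCells(generateCohort(cfg)))
    })
}

smallConfig <- function() defaultCohortConfig(cellsPerSample = 150)

# Minimal cohort wrapper around an explicit genes x cells count matrix.
toyCohort <- function(counts, sample = "s1", group = "RET",
                      positions = NULL) {
    PCPGCohort(counts,
               data.frame(sample_id = rep(sample, ncol(counts)),
                          mutation_group = rep(group, ncol(counts))),
               genePositions = positions)
}

# Random sparse integer count matrix with dimnames.
randomCounts <- function(nGenes, nCells, seed, lambda = 2) {
    set.seed(seed)
    m <- matrix(rpois(nGenes * nCells, lambda), nGenes, nCells,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("c%03d", seq_len(nCells))))
    m
}

# Exhaustive two-sided permutation p-value of the Wilcoxon rank-sum test:
# enumerates every assignment of n1 labels, handles ties through midranks.
# Pass precomputed utils::combn(n, n1) as `combs` to amortize enumeration.
exactRankSumP <- function(x, inGroup, combs = NULL) {
    r <- rank(x)
    n1 <- sum(inGroup)
    obs <- abs(sum(r[inGroup]) - n1 * (length(x) + 1) / 2)
    if (is.null(combs)) combs <- utils::combn(length(x), n1)
    stats <- abs(colSums(matrix(r[combs], nrow = n1)) -
                 n1 * (length(x) + 1) / 2)
    mean(stats >= obs - 1e-9)
}

combsFor <- function(n, n1) {
    memo(sprintf("combs_%d_%d", n, n1),
         function() utils::combn(n, n1))
}

# Exhaustive Viterbi oracle: enumerate all 3^n state paths of the same
# symmetric 3-state Gaussian HMM and return the most probable one.
bruteViterbi <- function(y, delta, sdEmit, pStay) {
    n <- length(y)
    means <- c(-delta, 0, delta)
    paths <- as.matrix(expand.grid(rep(list(1:3), n)))
    logp <- rep(log(1 / 3), nrow(paths))
    for (t in seq_len(n)) {
        logp <- logp + dnorm(y[t], means[paths[, t]], sdEmit, log = TRUE)
        if (t > 1) logp <- logp + ifelse(paths[, t] == paths[, t - 1],
                                         log(pStay), log((1 - pStay) / 2))
    }
    unname(paths[which.max(logp), ]) - 2L
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Truth matrix of planted CNV states aligned to a CNVProfile.
truthStates <- function(profile, cohort) {
    gt <- groundTruth(cohort)
    st <- cnvStates(profile)
    ann <- profile@genes
    truth <- matrix(0L, nrow(st), ncol(st), dimnames = dimnames(st))
    for (i in seq_len(nrow(gt$segments))) {
        s <- gt$segments[i, ]
        g <- paste0("NE:", s$sample_id)
        if (g %in% rownames(st))
            truth[g, ann$arm == s$arm] <- if (s$dosage < 1) -1L else 1L
    }
    truth
}

# Best overlap of each program's top genes with the planted program sets.
plantedIdentity <- function(programSet, cohort) {
    gt <- groundTruth(cohort)
    planted <- split(gt$program_genes$gene, gt$program_genes$program)
    tab <- programs(programSet)
    ids <- unique(tab$program_id)
    ov <- t(vapply(ids, function(id) {
        g <- tab$gene[tab$program_id == id]
        vapply(planted, function(pg) length(intersect(g, pg)), numeric(1))
    }, numeric(length(planted))))
    data.frame(program_id = ids, planted = apply(ov, 1L, which.max),
               overlap = apply(ov, 1L, max), stringsAsFactors = FALSE)
}

# One full-scale pipeline run shared by the acceptance tests.
acceptanceRun <- function() {
    memo("acceptanceRun", function() {
        outdir <- file.path(tempdir(), "acceptance_pipeline")
        man <- runPipeline(pipelineConfig(seed = 101), outdir = outdir)
        list(manifest = man, objects = attr(man, "objects"),
             outdir = outdir)
    })
}
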