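#' Default synthetic cohort configuration
#'
#' Returns a [CohortConfig-class] emulating the analyzed study design: an
#' 11-library cohort (5 RET + 6 SDHB) of which one RET library
#' (`excludedSample = "RET05"`) is dropped before tumor-cell analyses,
#' leaving 10 analyzed tumor samples; three major compartments
#' (neuroendocrine 63\%, immune 16\%, stromal 16\%) plus a small cortical
#' remainder (5\%); ten shared transcriptional programs of 50 genes each,
#' six active in both mutation groups and two specific to each group; a
#' patient-private expression signature per sample; and chromosomal dosage
#' segments — a 0.5x loss of arm 1p planted in the tumor cells of every
#' sample, plus one private whole-arm segment per sample.
#'
#' Sizes are desk scale: a miniature genome of 4 chromosomes x 500 genes
#' (p/q arms of 250 genes each, so the 101-gene smoothing window is
#' exercised) and 1000 cells per library by default.
#'
#' @param ... named overrides for any [CohortConfig-class] slot, e.g.
#'   `cellsPerSample = 200` for quick experiments.
#' @return a validated [CohortConfig-class].
#' @examples
#' cfg <- defaultCohortConfig(cellsPerSample = 50)
#' cfg
#' @export
defaultCohortConfig <- function(...) {
    privateArms <- c("2p", "2q", "3p", "3q", "4p", "4q")
    sampleIds <- c(sprintf("RET%02d", 1:5), sprintf("SDHB%02d", 1:6))
    private <- data.frame(
        arm = privateArms[(seq_along(sampleIds) - 1L) %% 6L + 1L],
        dosage = ifelse(seq_along(sampleIds) %% 2L == 1L, 1.5, 0.5),
        samples = sampleIds,
        stringsAsFactors = FALSE)
    cfg <- methods::new(
        "CohortConfig",
        nSamplesRET = 5L,
        nSamplesSDHB = 6L,
        cellsPerSample = 1000L,
        nGenes = 2000L,
        celltypeFractions = c(neuroendocrine = 0.63, immune = 0.16,
                              stromal = 0.16, cortical = 0.05),
        nSharedPrograms = 10L,
        programSize = 50L,
        programActivity = data.frame(
            program = 1:10,
            prob_RET  = c(rep(0.35, 6), 0.55, 0.55, 0.10, 0.10),
            prob_SDHB = c(rep(0.35, 6), 0.10, 0.10, 0.55, 0.55),
            effect = rep(3, 10)),
        cnvSegments = rbind(
            data.frame(arm = "1p", dosage = 0.5, samples = "all",
                       stringsAsFactors = FALSE),
            private),
        markerPanels = list(
            neuroendocrine = c("TH", "DBH", "CHGB"),
            immune = c("PTPRC", "CD163", "CD247"),
            stromal = c("COL4A1", "COL1A2"),
            cortical = c("CYP11A1", "CYP11B1")),
        markerFold = 8,
        typeSignatureSize = 100L,
        typeSignatureFold = 4,
        privateSignatureSize = 80L,
        privateSignatureFold = 2.5,
        libsizeMeanlog = log(2500),
        libsizeSdlog = 0.3,
        nbDispersion = 0.15,
        excludedSample = "RET05",
        seed = 20220815L)
    override <- list(...)
    for (nm in names(override)) {
        methods::slot(cfg, nm) <- if (is(methods::slot(cfg, nm), "integer"))
            as.integer(override[[nm]]) else override[[nm]]
    }
    methods::validObject(cfg)
    cfg
}

.sampleIds <- function(config) {
    c(sprintf("RET%02d", seq_len(config@nSamplesRET)),
      sprintf("SDHB%02d", seq_len(config@nSamplesSDHB)))
}

.sampleGroups <- function(config) {
    setNames(rep(c("RET", "SDHB"),
                 c(config@nSamplesRET, config@nSamplesSDHB)),
             .sampleIds(config))
}

# Deterministic gene universe shared by cohort and reference generation:
# gene ids and positions on a miniature genome, per-gene baseline expression,
# planted program gene sets, per-type and per-sample signatures, and the
# reference-only sympathoblast signature. All draws come from a seed derived
# from config@seed, so the same config always yields the same universe.
.buildUniverse <- function(config) {
    nGenes <- config@nGenes
    nChrom <- 4L
    perChrom <- nGenes %/% nChrom
    if (perChrom * nChrom != nGenes)
        stop("nGenes must be divisible by 4 (miniature genome model)")
    geneIds <- sprintf("GENE%04d", seq_len(nGenes))
    markers <- unlist(config@markerPanels, use.names = FALSE)
    # markers occupy the tail of the last chromosome's q arm, away from the
    # planted 1p segment
    geneIds[nGenes - rev(seq_along(markers)) + 1L] <- markers
    chrom <- rep(sprintf("chr%d", seq_len(nChrom)), each = perChrom)
    within <- rep(seq_len(perChrom), nChrom)
    half <- perChrom %/% 2L
    arm <- paste0(sub("chr", "", chrom), ifelse(within <= half, "p", "q"))
    ann <- data.frame(gene_id = geneIds, chromosome = chrom,
                      start = (within - 1L) * 10000L + 1L,
                      end = (within - 1L) * 10000L + 1000L,
                      arm = arm, stringsAsFactors = FALSE)

    set.seed(.deriveSeed(config@seed, 0L))
    baseline <- setNames(rlnorm(nGenes, meanlog = 0, sdlog = 1), geneIds)
    # canonical markers are near-exclusive: fixed moderate baseline, boosted
    # in their own compartment, silenced elsewhere (below)
    baseline[markers] <- 1
    # structured gene pools avoid arm 1p so planted dosage ground truth is
    # not confounded with transcriptional structure
    eligible <- setdiff(geneIds[arm != "1p"], markers)
    take <- function(pool, n) {
        if (n > length(pool)) stop("gene pool exhausted; increase nGenes")
        sample(pool, n)
    }
    programGenes <- list()
    pool <- eligible
    for (p in seq_len(config@nSharedPrograms)) {
        programGenes[[p]] <- sort(take(pool, config@programSize))
        pool <- setdiff(pool, programGenes[[p]])
    }
    types <- names(config@celltypeFractions)
    typeSignatures <- list()
    for (ty in types) {
        typeSignatures[[ty]] <- sort(take(pool, config@typeSignatureSize))
        pool <- setdiff(pool, typeSignatures[[ty]])
    }
    sympathoSig <- sort(take(pool, config@typeSignatureSize))
    pool <- setdiff(pool, sympathoSig)
    privateSignatures <- list()
    for (s in .sampleIds(config))
        privateSignatures[[s]] <- sort(take(pool, config@privateSignatureSize))

    # per-type base expression weights (genes, before library-size scaling)
    typeWeights <- matrix(rep(baseline, length(types)), nrow = length(types),
                          byrow = TRUE, dimnames = list(types, geneIds))
    offFold <- 0.05
    for (ty in types) {
        typeWeights[ty, markers] <- typeWeights[ty, markers] * offFold
        typeWeights[ty, config@markerPanels[[ty]]] <-
            baseline[config@markerPanels[[ty]]] * config@markerFold
        typeWeights[ty, typeSignatures[[ty]]] <-
            typeWeights[ty, typeSignatures[[ty]]] * config@typeSignatureFold
    }
    list(geneIds = geneIds, ann = ann, baseline = baseline,
         programGenes = programGenes, typeSignatures = typeSignatures,
         sympathoSig = sympathoSig, privateSignatures = privateSignatures,
         typeWeights = typeWeights)
}

# dosage multiplier per gene for one sample's tumor cells
.sampleDosage <- function(config, universe, sampleId) {
    dos <- rep(1, length(universe$geneIds))
    segs <- config@cnvSegments
    if (!nrow(segs)) return(dos)
    for (i in seq_len(nrow(segs))) {
        hit <- segs$samples[i] == "all" ||
            sampleId %in% strsplit(segs$samples[i], ",")[[1]]
        if (hit) dos[universe$ann$arm == segs$arm[i]] <-
                dos[universe$ann$arm == segs$arm[i]] * segs$dosage[i]
    }
    dos
}

#' Generate a synthetic single-nucleus cohort
#'
#' Draws counts gene-wise from a negative binomial (gamma-Poisson) whose
#' mean is `library_size x relative_expression(cell type, gene) x program
#' boost x dosage`: each cell's relative expression profile combines a
#' lognormal per-gene baseline with cell-type marker and signature boosts
#' and (for tumor cells) a patient-private signature; tumor cells activate
#' each shared program independently with a mutation-group-specific
#' probability, multiplying that program's genes by its fold effect; and
#' chromosomal dosage segments multiply tumor-cell means on the affected
#' arm. Ground truth (true cell types, active programs, segments, planted
#' gene sets) is recorded in `colData` and `metadata()$ground_truth`.
#'
#' Fixing `config@seed` fixes the cohort bit-for-bit.
#'
#' @param config a [CohortConfig-class], e.g. [defaultCohortConfig()].
#' @return a [PCPGCohort-class] with gene positions in `rowData`.
#' @examples
#' co <- generateCohort(defaultCohortConfig(cellsPerSample = 30))
#' co
#' @export
generateCohort <- function(config) {
    methods::validObject(config)
    uni <- .buildUniverse(config)
    set.seed(.deriveSeed(config@seed, 1L))
    samples <- .sampleIds(config)
    groups <- .sampleGroups(config)
    types <- names(config@celltypeFractions)
    act <- config@programActivity
    nP <- config@nSharedPrograms
    blocks <- list(); metas <- list()
    for (s in samples) {
        n <- config@cellsPerSample
        if (n == 0L) next
        cellTypes <- sample(types, n, replace = TRUE,
                            prob = config@celltypeFractions)
        w <- uni$typeWeights[cellTypes, , drop = FALSE]
        isNE <- cellTypes == "neuroendocrine"
        if (any(isNE) && config@privateSignatureSize > 0L) {
            sig <- uni$privateSignatures[[s]]
            w[isNE, sig] <- w[isNE, sig] * config@privateSignatureFold
        }
        rel <- w / rowSums(w)
        libsize <- rlnorm(n, config@libsizeMeanlog, config@libsizeSdlog)
        mu <- rel * libsize
        probs <- if (groups[[s]] == "RET") act$prob_RET else act$prob_SDHB
        active <- matrix(FALSE, n, nP)
        if (nP > 0L) {
            active <- matrix(runif(n * nP), n, nP) <
                matrix(probs, n, nP, byrow = TRUE)
            active[!isNE, ] <- FALSE
            for (p in seq_len(nP)) {
                on <- active[, p]
                if (any(on)) mu[on, uni$programGenes[[p]]] <-
                        mu[on, uni$programGenes[[p]]] * act$effect[p]
            }
        }
        dos <- .sampleDosage(config, uni, s)
        if (any(isNE) && any(dos != 1))
            mu[isNE, ] <- sweep(mu[isNE, , drop = FALSE], 2L, dos, `*`)
        counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                                 size = 1 / config@nbDispersion),
                         nrow = n)
        dimnames(counts) <- list(sprintf("%s_cell%04d", s, seq_len(n)),
                                 uni$geneIds)
        blocks[[s]] <- methods::as(Matrix::Matrix(t(counts), sparse = TRUE),
                                   "generalMatrix")
        metas[[s]] <- data.frame(
            sample_id = s, mutation_group = groups[[s]],
            true_cell_type = cellTypes,
            true_program_ids = vapply(seq_len(n), function(i) {
                paste(which(active[i, ]), collapse = ",")
            }, character(1)),
            stringsAsFactors = FALSE)
    }
    if (length(blocks)) {
        m <- do.call(cbind, blocks)
        meta <- do.call(rbind, metas)
        rownames(meta) <- colnames(m)
    } else {
        m <- Matrix::Matrix(0L, nrow = config@nGenes, ncol = 0L, sparse = TRUE,
                            dimnames = list(uni$geneIds, character()))
        meta <- data.frame(sample_id = character(), mutation_group = character(),
                           true_cell_type = character(),
                           true_program_ids = character())
    }
    cohort <- PCPGCohort(m, meta, genePositions = uni$ann)
    segs <- do.call(rbind, lapply(samples, function(s) {
        dos <- config@cnvSegments
        hit <- dos$samples == "all" |
            vapply(dos$samples, function(x) s %in% strsplit(x, ",")[[1]],
                   logical(1))
        if (!any(hit)) return(NULL)
        data.frame(sample_id = s, arm = dos$arm[hit], dosage = dos$dosage[hit],
                   stringsAsFactors = FALSE)
    }))
    metadata(cohort)$ground_truth <- list(
        program_genes = data.frame(
            program = rep(seq_len(nP),
                          each = if (nP) config@programSize else 0L),
            gene = unlist(uni$programGenes)),
        segments = segs,
        type_signatures = uni$typeSignatures,
        private_signatures = uni$privateSignatures,
        marker_panels = config@markerPanels)
    metadata(cohort)$config_seed <- config@seed
    cohort
}

#' Generate a labeled synthetic reference dataset
#'
#' Builds a reference cohort on the same gene universe as
#' [generateCohort()] (same `config`, hence shared gene ids and baseline)
#' with five labeled cell types for similarity mapping: `chromaffin`
#' (the neuroendocrine expression profile), `sympathoblast` (its own
#' signature), `bridge` (the geometric mean of the chromaffin and
#' sympathoblast profiles — a developmental intermediate), and `immune` /
#' `stromal` counterparts of the microenvironment. No programs and no
#' dosage segments are planted.
#'
#' @param config the [CohortConfig-class] whose universe to reuse.
#' @param nCellsPerType cells per reference type.
#' @param seed RNG seed for the reference draws (the gene universe itself
#'   is fixed by `config@seed`).
#' @return a [PCPGCohort-class] with a `cell_type` column in `colData`.
#' @export
generateReference <- function(config, nCellsPerType = 200L,
                              seed = config@seed + 1L) {
    methods::validObject(config)
    uni <- .buildUniverse(config)
    wChrom <- uni$typeWeights["neuroendocrine", ]
    wSym <- uni$baseline
    allMarkers <- unlist(config@markerPanels, use.names = FALSE)
    wSym[allMarkers] <- wSym[allMarkers] * 0.05
    wSym[uni$sympathoSig] <- wSym[uni$sympathoSig] * config@typeSignatureFold
    wSym[config@markerPanels$neuroendocrine] <-
        uni$baseline[config@markerPanels$neuroendocrine] *
        sqrt(config@markerFold)
    profiles <- rbind(
        chromaffin = wChrom,
        sympathoblast = wSym,
        bridge = sqrt(wChrom * wSym),
        immune = uni$typeWeights["immune", ],
        stromal = uni$typeWeights["stromal", ])
    set.seed(.deriveSeed(seed, 2L))
    n <- as.integer(nCellsPerType)
    blocks <- list(); labels <- character()
    for (ty in rownames(profiles)) {
        rel <- profiles[ty, ] / sum(profiles[ty, ])
        libsize <- rlnorm(n, config@libsizeMeanlog, config@libsizeSdlog)
        mu <- outer(libsize, rel)
        counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                                 size = 1 / config@nbDispersion), nrow = n)
        dimnames(counts) <- list(sprintf("ref_%s_%04d", ty, seq_len(n)),
                                 uni$geneIds)
        blocks[[ty]] <- methods::as(Matrix::Matrix(t(counts), sparse = TRUE),
                                    "generalMatrix")
        labels <- c(labels, rep(ty, n))
    }
    m <- do.call(cbind, blocks)
    meta <- data.frame(sample_id = "reference",
                       mutation_group = NA_character_,
                       cell_type = labels, stringsAsFactors = FALSE)
    rownames(meta) <- colnames(m)
    PCPGCohort(m, meta, genePositions = uni$ann)
}
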