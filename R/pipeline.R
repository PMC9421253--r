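#' Assemble a pipeline configuration
#'
#' Returns the full pipeline configuration as a named list: every stage
#' parameter has a default matching the analysis conventions the package
#' implements (QC bounds 0.10/2.50, scale total 10000, 15 PCs, clustering
#' resolution 0.3, marker thresholds 0.25/0.25 then p < 0.05 and
#' |log2FC| > 1.2, CNV window 101, 28 NMF factors, top-50 program genes,
#' automatic metaprogram cut, elastic-net alpha 0.6). Values from a YAML
#' `file` override the defaults, and `...` overrides both (top-level keys
#' are merged element-wise, so `cluster = list(resolution = 0.5)` changes
#' only the resolution).
#'
#' The variable-gene count defaults to 1500 here (the synthetic miniature
#' genome has 2000 genes); [selectHVG()] itself defaults to 4000 for
#' full-size data.
#'
#' @param file optional YAML file.
#' @param ... named overrides.
#' @return named list with class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(file = NULL, ...) {
    cfg <- list(
        input_dir = NULL,
        synthetic = list(),
        excluded_samples = "RET05",
        qc = list(low_frac = 0.10, high_frac = 2.50),
        normalize = list(scale_total = 10000),
        hvg = list(n = 1500, bins = 20),
        scale = list(clip = 10),
        pca = list(n_components = 15),
        cluster = list(k_neighbors = 20, resolution = 0.3),
        markers = list(min_pct = 0.25, min_logfc = 0.25, p_cutoff = 0.05,
                       log2fc_cutoff = 1.2),
        panels = NULL,
        cnv = list(window = 101, clamp = 3, delta = 0.15, p_stay = 0.99),
        nmf = list(k = 28, top_n = 50, max_iter = 500, tol = 1e-5,
                   input = "centered"),
        metaprograms = list(n_meta = "auto", n_bins = 25, n_ctrl = 100,
                            top_n = 50),
        similarity = list(alpha = 0.6, lambda = "auto", folds = 5,
                          cells_per_type = 200),
        seed = 1,
        outdir = NULL)
    apply_over <- function(cfg, over) {
        for (nm in names(over)) {
            if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
                for (sub in names(over[[nm]]))
                    cfg[[nm]][[sub]] <- over[[nm]][[sub]]
            } else cfg[[nm]] <- over[[nm]]
        }
        cfg
    }
    if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file))
    cfg <- apply_over(cfg, list(...))
    structure(cfg, class = "pipelineConfig")
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full heterogeneity pipeline
#'
#' Executes all stages in order on either a counts directory
#' (`config$input_dir`) or a freshly simulated cohort: simulate/load, QC
#' filter, normalization, variable genes, scaling, PCA, SNN-Louvain
#' clustering, marker detection, cell-type annotation, composition summary;
#' then, on cells annotated neuroendocrine and not in
#' `config$excluded_samples`: inferred CNV (all other annotated cells as
#' reference), per-sample NMF and program extraction, cohort-wide program
#' scoring, metaprogram clustering and scoring, mutation-group comparison;
#' finally elastic-net similarity of query cells to a labeled synthetic
#' reference generated on the same gene universe. Every stochastic step
#' draws its seed from `config$seed`, so a fixed config reproduces every
#' output byte-for-byte.
#'
#' Each stage writes its tables under `outdir` and is timed; the run
#' manifest (config snapshot, per-output MD5 hashes, stage wall-clock,
#' seeds, package versions) is written last as `manifest.json`. A stage
#' failure aborts with the stage name; outputs of completed stages remain
#' on disk.
#'
#' @param config a [pipelineConfig()] list.
#' @param outdir output directory (overrides `config$outdir`).
#' @return the manifest, invisibly. Intermediate R objects are returned in
#'   the `"objects"` attribute for interactive use.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = config$outdir) {
    if (is.null(outdir)) stop("an output directory is required")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    master <- as.integer(config$seed)
    manifest <- list(config = unclass(config),
                     versions = list(
                         R = as.character(getRversion()),
                         pcpgHet = as.character(utils::packageVersion("pcpgHet"))),
                     stages = list())
    obj <- new.env(parent = emptyenv())
    stage <- function(name, fun) {
        t0 <- proc.time()[["elapsed"]]
        files <- tryCatch(fun(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        files <- as.character(files)
        hashes <- list()
        if (length(files)) {
            hashes <- as.list(tools::md5sum(files))
            names(hashes) <- basename(names(hashes))
        }
        manifest$stages[[name]] <<- list(
            status = "ok",
            seconds = round(proc.time()[["elapsed"]] - t0, 2),
            outputs = hashes)
        message(sprintf("[pipeline] %-14s ok (%.1fs)", name,
                        proc.time()[["elapsed"]] - t0))
    }

    stage("simulate", function() {
        syn <- config$synthetic
        syn$seed <- if (!is.null(syn$seed)) syn$seed
                    else .deriveSeed(master, 10L)
        obj$cohortConfig <- do.call(defaultCohortConfig, syn)
        obj$cohort <- if (!is.null(config$input_dir))
            readCountsDir(config$input_dir)
        else generateCohort(obj$cohortConfig)
        character()
    })
    stage("qc", function() {
        obj$cohort <- filterCells(obj$cohort, config$qc$low_frac,
                                  config$qc$high_frac)
        obj$cohort <- normalizeLog(obj$cohort,
                                   config$normalize$scale_total)
        .writeTSV(data.frame(metric = c("cells_after_filter", "genes"),
                             value = dim(obj$cohort)[c(2, 1)]),
                  file.path(outdir, "qc_summary.tsv"))
    })
    stage("hvg", function() {
        hv <- selectHVG(obj$cohort, n = config$hvg$n, nBins = config$hvg$bins)
        obj$hvgGenes <- hv$gene[hv$selected]
        .writeTSV(hv[hv$selected, ], file.path(outdir, "hvg.tsv"))
    })
    stage("cluster", function() {
        scaled <- scaleGenes(obj$cohort, obj$hvgGenes,
                             clip = config$scale$clip)
        obj$pca <- runPCA(scaled, nComponents = config$pca$n_components)
        obj$clustering <- clusterGraph(
            obj$pca, kNeighbors = config$cluster$k_neighbors,
            resolution = config$cluster$resolution,
            seed = .deriveSeed(master, 20L))
        .writeTSV(data.frame(cell_id = colnames(obj$cohort),
                             cluster = obj$clustering$labels),
                  file.path(outdir, "clusters.tsv"))
    })
    stage("markers", function() {
        mk <- findMarkers(obj$cohort, obj$clustering$labels,
                          minPct = config$markers$min_pct,
                          minLogFC = config$markers$min_logfc,
                          pCutoff = config$markers$p_cutoff,
                          log2fcCutoff = config$markers$log2fc_cutoff)
        .writeTSV(mk, file.path(outdir, "markers.tsv"))
    })
    stage("annotate", function() {
        panels <- if (!is.null(config$panels)) config$panels
                  else obj$cohortConfig@markerPanels
        ann <- annotateCellTypes(obj$cohort, obj$clustering$labels, panels)
        obj$cellType <- ann$cellType
        comp <- compositionSummary(ann$cellType,
                                   colData(obj$cohort)$sample_id)
        c(.writeTSV(ann$clusters, file.path(outdir, "celltypes.tsv")),
          .writeTSV(comp, file.path(outdir, "composition.tsv")))
    })
    stage("cnv", function() {
        cd <- colData(obj$cohort)
        use <- !(cd$sample_id %in% config$excluded_samples)
        sub <- obj$cohort[, use]
        isNE <- obj$cellType[use] == "neuroendocrine"
        grp <- ifelse(isNE, paste0("NE:", colData(sub)$sample_id),
                      obj$cellType[use])
        refGroups <- unique(grp[!isNE])
        centered <- centerOnReference(sub, which(!isNE),
                                      clamp = config$cnv$clamp)
        smoothed <- smoothGenomic(centered,
                                  as.data.frame(rowData(sub)) |>
                                      (\(d) { d$gene_id <- rownames(sub); d })(),
                                  window = config$cnv$window)
        obj$cnv <- callCNVStates(smoothed, grp, refGroups,
                                 delta = config$cnv$delta,
                                 pStay = config$cnv$p_stay)
        st <- cnvStates(obj$cnv)
        stDf <- data.frame(group = rep(rownames(st), ncol(st)),
                           gene = rep(colnames(st), each = nrow(st)),
                           state = as.vector(st))
        c(.writeTSV(stDf, file.path(outdir, "cnv_states.tsv")),
          .writeTSV(armSummary(obj$cnv),
                    file.path(outdir, "cnv_arm_summary.tsv")))
    })
    stage("nmf", function() {
        cd <- colData(obj$cohort)
        tumor <- obj$cellType == "neuroendocrine" &
            !(cd$sample_id %in% config$excluded_samples)
        obj$tumorCells <- colnames(obj$cohort)[tumor]
        lam <- assay(obj$cohort, "logcounts")
        results <- list()
        for (s in sort(unique(cd$sample_id[tumor]))) {
            cells <- colnames(obj$cohort)[tumor & cd$sample_id == s]
            x <- prepareNMFInput(lam[obj$hvgGenes, cells, drop = FALSE],
                                 method = config$nmf$input)
            results[[s]] <- nmfFactorize(
                x, k = config$nmf$k,
                seed = .deriveSeed(master, 30L + match(s, sort(unique(cd$sample_id)))),
                maxIter = config$nmf$max_iter, tol = config$nmf$tol,
                sampleId = s)
        }
        obj$programSet <- extractPrograms(results, topN = config$nmf$top_n)
        .writeTSV(programs(obj$programSet), file.path(outdir, "programs.tsv"))
    })
    stage("metaprograms", function() {
        nmTumor <- .cellsByGenes(obj$cohort[, obj$tumorCells], "logcounts")
        obj$programScores <- scoreAllPrograms(
            nmTumor, obj$programSet, nBins = config$metaprograms$n_bins,
            nCtrl = config$metaprograms$n_ctrl,
            seed = .deriveSeed(master, 40L))
        obj$metaprograms <- clusterMetaprograms(
            obj$programScores, obj$programSet,
            nMeta = config$metaprograms$n_meta)
        obj$metaprograms <- scoreMetaprograms(
            nmTumor, obj$metaprograms, topN = config$metaprograms$top_n,
            nBins = config$metaprograms$n_bins,
            nCtrl = config$metaprograms$n_ctrl,
            seed = .deriveSeed(master, 41L))
        assign <- programAssignment(obj$metaprograms)
        scores <- metaprogramScores(obj$metaprograms)
        c(.writeTSV(data.frame(program_id = names(assign),
                               metaprogram = as.integer(assign)),
                    file.path(outdir, "metaprogram_assignment.tsv")),
          .writeTSV(metaprogramGenes(obj$metaprograms),
                    file.path(outdir, "metaprogram_genes.tsv")),
          .writeTSV(data.frame(cell_id = rownames(scores),
                               round(scores, 6)),
                    file.path(outdir, "metaprogram_cell_scores.tsv")))
    })
    stage("compare", function() {
        grp <- colData(obj$cohort)[obj$tumorCells, "mutation_group"]
        cmp <- compareGroups(metaprogramScores(obj$metaprograms), grp)
        .writeTSV(cmp, file.path(outdir, "group_comparison.tsv"))
    })
    stage("similarity", function() {
        ref <- generateReference(obj$cohortConfig,
                                 nCellsPerType = config$similarity$cells_per_type,
                                 seed = .deriveSeed(master, 50L))
        ref <- normalizeLog(ref, config$normalize$scale_total)
        refMat <- .cellsByGenes(ref, "logcounts")[, obj$hvgGenes, drop = FALSE]
        model <- trainSimilarityModel(
            refMat, colData(ref)$cell_type,
            alpha = config$similarity$alpha,
            lambda = config$similarity$lambda,
            nfolds = config$similarity$folds,
            seed = .deriveSeed(master, 51L))
        qry <- .cellsByGenes(obj$cohort, "logcounts")[, obj$hvgGenes,
                                                      drop = FALSE]
        byType <- predictSimilarity(model, qry, obj$cellType)
        tum <- obj$tumorCells
        bySample <- predictSimilarity(
            model, qry[tum, , drop = FALSE],
            colData(obj$cohort)[tum, "sample_id"])
        asDf <- function(m) data.frame(group = rownames(m),
                                       round(m, 6), check.names = FALSE)
        c(.writeTSV(asDf(byType$groupMeans),
                    file.path(outdir, "similarity_by_type.tsv")),
          .writeTSV(asDf(bySample$groupMeans),
                    file.path(outdir, "similarity_by_sample.tsv")))
    })
    manifest$seeds <- list(master = master)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(manifest, "objects") <- as.list(obj)
    invisible(manifest)
}

#' Write the miniature fixture tree used by the test suite
#'
#' Materializes, under `path`, the hand-computable toys the unit tests are
#' built around: a 5-cell QC toy whose detected-gene counts are
#' 100/1000/1000/1000/5000 (library mean 1620, so exactly the three
#' 1000-gene cells survive the 10\%-250\% filter), an exactly rank-2
#' non-negative matrix (`W0 %*% H0`) for NMF reconstruction, and a one-
#' chromosome step profile (first half -1, second half +1) with gene
#' positions for the smoothing ramp.
#'
#' @param seed RNG seed for the random parts of the toys.
#' @param path output directory.
#' @return invisible list of the written paths.
#' @export
makeFixtures <- function(seed, path) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    set.seed(as.integer(seed))
    out <- list()

    # QC toy: detected-gene counts 100/1000/1000/1000/5000 in one library
    det <- c(100L, 1000L, 1000L, 1000L, 5000L)
    nGenes <- 5000L
    m <- Matrix::sparseMatrix(
        i = unlist(lapply(det, seq_len)),
        j = rep(seq_along(det), det),
        x = 1, dims = c(nGenes, length(det)),
        dimnames = list(sprintf("G%04d", seq_len(nGenes)),
                        paste0("cell", seq_along(det))))
    qcDir <- file.path(path, "qc_toy")
    toy <- PCPGCohort(m, data.frame(sample_id = rep("lib1", 5),
                                    mutation_group = rep("RET", 5)))
    out$qc <- writeCountsDir(toy, qcDir)

    # NMF toy: exact rank-2 non-negative matrix
    W0 <- matrix(runif(40 * 2), 40, 2)
    H0 <- matrix(runif(2 * 25), 2, 25)
    x <- W0 %*% H0
    dimnames(x) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:25))
    nmfFile <- file.path(path, "nmf_rank2.tsv")
    write.table(round(x, 10), nmfFile, sep = "\t", quote = FALSE)
    out$nmf <- nmfFile

    # CNV toy: step profile on one chromosome of 200 genes
    nG <- 200L
    ann <- data.frame(gene_id = sprintf("s%03d", seq_len(nG)),
                      chromosome = "chr1",
                      start = seq_len(nG) * 1000L,
                      end = seq_len(nG) * 1000L + 500L,
                      arm = rep(c("1p", "1q"), each = nG %/% 2L))
    step <- rep(c(-1, 1), each = nG %/% 2L)
    cnvDir <- file.path(path, "cnv_toy")
    dir.create(cnvDir, showWarnings = FALSE)
    out$cnv_positions <- .writeTSV(ann, file.path(cnvDir, "positions.tsv"))
    out$cnv_profile <- .writeTSV(
        data.frame(gene_id = ann$gene_id, value = step),
        file.path(cnvDir, "step_profile.tsv"))
    invisible(out)
}
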