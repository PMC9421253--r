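#' @import methods
#' @importFrom stats var sd median quantile rnorm rbinom rnbinom rlnorm runif
#'   cor dist hclust cutree prcomp p.adjust pnorm dnorm wilcox.test
#'   predict setNames
#' @importFrom utils head read.delim write.table
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim
#'   reducedDim<- reducedDims
#' @importFrom SummarizedExperiment assay assay<- assays assayNames colData
#'   colData<- rowData rowData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' PCPGCohort: a validated single-nucleus cohort container
#'
#' Extends [SingleCellExperiment::SingleCellExperiment] with validity
#' guarantees used throughout the package: a `"counts"` assay of
#' non-negative integral values (cells are columns, genes rows, the
#' Bioconductor convention), unique gene and cell identifiers, and per-cell
#' `sample_id` and `mutation_group` columns in `colData`. Gene genomic
#' positions, when available, live in `rowData` (`chromosome`, `start`,
#' `end`, `arm`). Simulated ground truth is stored in `metadata()$ground_truth`.
#'
#' @seealso [PCPGCohort()], [generateCohort()], [readCountsDir()]
#' @export
setClass("PCPGCohort", contains = "SingleCellExperiment")

setValidity("PCPGCohort", function(object) {
    msg <- character()
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        x <- assay(object, "counts")
        vals <- if (methods::is(x, "sparseMatrix")) x@x else as.numeric(x)
        if (length(vals) && any(vals < 0))
            msg <- c(msg, "counts must be non-negative")
        if (length(vals) && any(vals != round(vals)))
            msg <- c(msg, "counts must be integral")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "cell ids (colnames) must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be unique")
    if (!all(c("sample_id", "mutation_group") %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain sample_id and mutation_group")
    if (length(msg)) msg else TRUE
})

#' Construct a PCPGCohort
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of raw
#'   counts; non-negative integers. Must carry unique dimnames.
#' @param cellMeta data.frame with one row per cell (aligned by order),
#'   containing at least `sample_id` and `mutation_group` (values `"RET"`,
#'   `"SDHB"` or `NA`).
#' @param genePositions optional gene-annotation data.frame as returned by
#'   [readGenePositions()]; matched to `rownames(counts)` by `gene_id` and
#'   stored in `rowData`.
#' @return a [PCPGCohort-class] object.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' co <- PCPGCohort(m, data.frame(sample_id = c("s1", "s1"),
#'                                mutation_group = c("RET", "RET")))
#' co
#' @export
PCPGCohort <- function(counts, cellMeta, genePositions = NULL) {
    if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
        (ncol(counts) > 0 && is.null(colnames(counts))))
        stop("counts must have gene rownames and cell colnames")
    counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
    cd <- DataFrame(cellMeta, row.names = colnames(counts))
    sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
    if (!is.null(genePositions)) {
        idx <- match(rownames(counts), genePositions$gene_id)
        if (anyNA(idx))
            stop("genePositions is missing ", sum(is.na(idx)), " gene(s)")
        rowData(sce) <- DataFrame(genePositions[idx, , drop = FALSE],
                                  row.names = rownames(counts))
    }
    methods::new("PCPGCohort", sce)
}

#' NMF factorization result for one sample
#'
#' Holds the non-negative factors of one per-sample factorization:
#' `W` (genes x k loadings, columns scaled to unit L2 norm) and `H`
#' (k x cells activities), together with the per-iteration Frobenius
#' objective trace (non-increasing by construction of the multiplicative
#' updates).
#'
#' @seealso [nmfFactorize()]
#' @export
setClass("NMFResult", slots = c(
    sampleId  = "character",
    W         = "matrix",
    H         = "matrix",
    k         = "integer",
    objective = "numeric",
    seed      = "integer"
))

setValidity("NMFResult", function(object) {
    msg <- character()
    if (any(object@W < 0) || any(object@H < 0))
        msg <- c(msg, "W and H must be non-negative")
    if (ncol(object@W) != object@k || nrow(object@H) != object@k)
        msg <- c(msg, "W/H dimensions must match k")
    d <- diff(object@objective)
    if (length(d) && any(d > 1e-8 * object@objective[1]))
        msg <- c(msg, "objective trace must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' A set of transcriptional programs (top NMF genes per factor)
#'
#' One program per (sample, factor): the `topN` genes with the highest
#' loading in that factor's `W` column, stored long-format in `programs`
#' with columns `program_id`, `sample_id`, `factor`, `rank`, `gene`,
#' `loading` (loading-descending within a program).
#'
#' @seealso [extractPrograms()]
#' @export
setClass("ProgramSet", slots = c(programs = "data.frame", topN = "integer"))

setValidity("ProgramSet", function(object) {
    need <- c("program_id", "sample_id", "factor", "rank", "gene", "loading")
    if (!all(need %in% colnames(object@programs)))
        return(paste("programs must have columns:", paste(need, collapse = ", ")))
    TRUE
})

#' Metaprograms: clusters of correlated programs
#'
#' `assignment` maps each program id to a metaprogram; `genes` lists each
#' metaprogram's genes ranked by their frequency of membership among the
#' recurrent constituent programs (ties broken by mean within-program
#' loading rank); `cellScores` holds per-cell module scores for each
#' metaprogram; `silhouette` records the mean silhouette width at each
#' candidate cut; `recurrent` flags, per program, whether it passed the
#' cross-sample recurrence filter and therefore helped define the clusters.
#'
#' @seealso [clusterMetaprograms()], [scoreMetaprograms()]
#' @export
setClass("MetaprogramSet", slots = c(
    assignment = "integer",
    nMeta      = "integer",
    genes      = "data.frame",
    cellScores = "matrix",
    silhouette = "data.frame",
    recurrent  = "logical"
))

setValidity("MetaprogramSet", function(object) {
    msg <- character()
    if (is.null(names(object@assignment)))
        msg <- c(msg, "assignment must be named by program_id")
    if (nrow(object@genes) &&
        (any(object@genes$frequency <= 0) || any(object@genes$frequency > 1)))
        msg <- c(msg, "gene frequencies must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Expression-inferred copy-number profile
#'
#' Group-averaged, reference-centered and genomically smoothed expression
#' (`smoothed`, groups x genes in canonical genomic order, log-ratio units)
#' with per-gene hidden-state calls (`states`, -1 = loss, 0 = neutral,
#' +1 = gain) from a three-state Gaussian HMM, plus the gene annotation and
#' the parameters used.
#'
#' @seealso [callCNVStates()], [armSummary()]
#' @export
setClass("CNVProfile", slots = c(
    smoothed = "matrix",
    states   = "matrix",
    genes    = "data.frame",
    params   = "list"
))

setValidity("CNVProfile", function(object) {
    msg <- character()
    if (!identical(dim(object@smoothed), dim(object@states)))
        msg <- c(msg, "smoothed and states must be aligned")
    if (any(!is.finite(object@smoothed)))
        msg <- c(msg, "smoothed values must be finite")
    if (length(st <- object@states) && !all(st %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "states must be -1, 0 or 1")
    if (length(msg)) msg else TRUE
})

#' Elastic-net similarity model
#'
#' One-vs-rest binomial logistic regressions (one per reference cell type)
#' with elastic-net penalty, fitted on reference-standardized features.
#' `coefficients` is genes x types; query cells are standardized with the
#' reference means/sds stored here, never their own.
#'
#' @seealso [trainSimilarityModel()], [predictSimilarity()]
#' @export
setClass("SimilarityModel", slots = c(
    coefficients = "matrix",
    intercepts   = "numeric",
    alpha        = "numeric",
    lambda       = "numeric",
    genes        = "character",
    geneMeans    = "numeric",
    geneSds      = "numeric",
    types        = "character"
))

setValidity("SimilarityModel", function(object) {
    msg <- character()
    if (nrow(object@coefficients) != length(object@genes))
        msg <- c(msg, "coefficient rows must align to the shared gene list")
    if (ncol(object@coefficients) != length(object@types))
        msg <- c(msg, "coefficient columns must align to types")
    if (object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "alpha must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' Every knob of the synthetic cohort generator. The defaults (see
#' [defaultCohortConfig()]) emulate an eleven-sample PCPG-like cohort:
#' 5 RET + 6 SDHB libraries, three major cell compartments
#' (neuroendocrine ~63\%, immune ~16\%, stromal ~16\%, a small cortical
#' remainder), ten shared transcriptional programs with mutation-group
#' specific activity, patient-private expression signatures, and planted
#' chromosomal dosage segments including a 1p loss carried by every tumor
#' sample.
#'
#' @seealso [defaultCohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig", slots = c(
    nSamplesRET          = "integer",
    nSamplesSDHB         = "integer",
    cellsPerSample       = "integer",
    nGenes               = "integer",
    celltypeFractions    = "numeric",
    nSharedPrograms      = "integer",
    programSize          = "integer",
    programActivity      = "data.frame",
    cnvSegments          = "data.frame",
    markerPanels         = "list",
    markerFold           = "numeric",
    typeSignatureSize    = "integer",
    typeSignatureFold    = "numeric",
    privateSignatureSize = "integer",
    privateSignatureFold = "numeric",
    libsizeMeanlog       = "numeric",
    libsizeSdlog         = "numeric",
    nbDispersion         = "numeric",
    excludedSample       = "character",
    seed                 = "integer"
))

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (abs(sum(object@celltypeFractions) - 1) > 1e-9)
        msg <- c(msg, "celltypeFractions must sum to 1")
    if (any(object@celltypeFractions < 0))
        msg <- c(msg, "celltypeFractions must be non-negative")
    if (nrow(object@cnvSegments) && any(object@cnvSegments$dosage <= 0))
        msg <- c(msg, "dosage factors must be > 0")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be > 0")
    if (as.numeric(object@programSize) * object@nSharedPrograms >
        object@nGenes)
        msg <- c(msg, "program_size x n_shared_programs exceeds n_genes")
    if (length(msg)) msg else TRUE
})
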