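#' Read a 10x-style counts directory
#'
#' Reads a plain Matrix Market triplet layout: `matrix.mtx` (genes x cells,
#' the 10x on-disk convention), `barcodes.tsv` (one cell barcode per line),
#' `features.tsv` (one gene id per line) and, if present, `cells.tsv`
#' (tab-separated per-cell metadata with a header; row i describes barcode i)
#' and `genes_positions.tsv` (see [readGenePositions()]). Counts are kept
#' genes x cells in the returned object (the Bioconductor convention);
#' analysis code transposes to cells x genes where needed.
#'
#' @param path directory containing the files above.
#' @return a [PCPGCohort-class].
#' @details Fractional values in the triplet file are a hard error: raw
#'   counts are integral by definition and a non-integer entry indicates a
#'   corrupted or already-normalized file.
#' @export
readCountsDir <- function(path) {
    need <- c("matrix.mtx", "barcodes.tsv", "features.tsv")
    for (f in need) {
        if (!file.exists(file.path(path, f)))
            stop("missing required file: ", file.path(path, f))
    }
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    if (methods::is(m, "nsparseMatrix"))  # pattern matrix when empty
        m <- methods::as(m, "dsparseMatrix")
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    features <- readLines(file.path(path, "features.tsv"))
    if (nrow(m) != length(features) || ncol(m) != length(barcodes))
        stop("matrix dimensions (", nrow(m), " x ", ncol(m),
             ") do not match sidecars (", length(features), " genes, ",
             length(barcodes), " cells)")
    vals <- methods::as(m, "CsparseMatrix")@x
    if (length(vals) && any(vals != round(vals)))
        stop("non-integer count found in matrix.mtx; raw counts must be integral")
    dimnames(m) <- list(features, barcodes)
    cellsFile <- file.path(path, "cells.tsv")
    if (file.exists(cellsFile)) {
        meta <- read.delim(cellsFile, stringsAsFactors = FALSE)
        if (nrow(meta) != length(barcodes))
            stop("cells.tsv has ", nrow(meta), " rows for ",
                 length(barcodes), " barcodes")
    } else {
        meta <- data.frame(sample_id = rep(NA_character_, length(barcodes)),
                           mutation_group = rep(NA_character_, length(barcodes)))
    }
    posFile <- file.path(path, "genes_positions.tsv")
    pos <- if (file.exists(posFile)) readGenePositions(posFile) else NULL
    PCPGCohort(m, meta, genePositions = pos)
}

#' Write a cohort as a 10x-style counts directory
#'
#' Inverse of [readCountsDir()]: writes `matrix.mtx` (genes x cells),
#' `barcodes.tsv`, `features.tsv`, a `cells.tsv` with the full `colData`,
#' and `genes_positions.tsv` when the cohort carries gene coordinates.
#' Lossless for counts, identifiers and cell metadata.
#'
#' @param cohort a [PCPGCohort-class].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
writeCountsDir <- function(cohort, path) {
    .assertCohort(cohort)
    ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                         showWarnings = FALSE)
    if (!ok || file.access(path, mode = 2L) != 0L)
        stop("cannot write to directory: ", path)
    m <- assay(cohort, "counts")
    Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(as.character(colnames(cohort)),
               file.path(path, "barcodes.tsv"))
    writeLines(as.character(rownames(cohort)),
               file.path(path, "features.tsv"))
    meta <- as.data.frame(colData(cohort))
    write.table(meta, file.path(path, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rd <- as.data.frame(rowData(cohort))
    if (all(c("chromosome", "start", "end") %in% colnames(rd))) {
        rd$gene_id <- rownames(cohort)
        keep <- intersect(c("gene_id", "chromosome", "start", "end", "arm"),
                          colnames(rd))
        write.table(rd[, keep], file.path(path, "genes_positions.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a gene genomic-position table
#'
#' Tab-separated with a header and at least the columns `gene_id`,
#' `chromosome`, `start`, `end`; an optional `arm` column (e.g. `"1p"`)
#' enables arm-level copy-number summaries. Coordinates are 1-based
#' inclusive base pairs (GTF convention). Rows are returned in the canonical
#' order used for genomic smoothing: chromosome (string sort), then start,
#' then `gene_id` — so the result does not depend on input row order.
#'
#' @param path path to the TSV.
#' @return data.frame with one validated row per gene, in canonical order.
#' @export
readGenePositions <- function(path) {
    if (!file.exists(path)) stop("missing required file: ", path)
    ann <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chromosome", "start", "end")
    if (!all(need %in% colnames(ann)))
        stop("gene position table must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(ann$gene_id))
        stop("duplicated gene_id in gene position table: ",
             paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
    if (any(ann$start < 1) || any(ann$end < 1))
        stop("coordinates must be >= 1 (1-based inclusive)")
    if (any(ann$start > ann$end))
        stop("start > end for gene(s): ",
             paste(ann$gene_id[ann$start > ann$end], collapse = ", "))
    ann[.canonicalGeneOrder(ann), , drop = FALSE] |>
        (\(x) { rownames(x) <- NULL; x })()
}
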