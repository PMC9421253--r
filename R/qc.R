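#' Per-library cell quality filter
#'
#' For each library (`sample_id`), computes the mean number of detected
#' genes per cell `m` on the unfiltered library (single pass) and retains
#' cells whose detected-gene count lies within `[lowFrac * m, highFrac * m]`
#' (defaults: 10\% and 250\% of the library mean). Filtering is independent
#' across libraries.
#'
#' Re-running the filter on already-filtered data recomputes `m` on the
#' retained cells and may therefore remove additional cells; the filter is
#' idempotent only with respect to the thresholds of the original pass.
#'
#' @param cohort a [PCPGCohort-class].
#' @param lowFrac,highFrac lower/upper bounds as fractions of the library
#'   mean detected-gene count; `0 <= lowFrac < highFrac`.
#' @return the cohort restricted to retained cells.
#' @export
filterCells <- function(cohort, lowFrac = 0.10, highFrac = 2.50) {
    .assertCohort(cohort)
    if (!(lowFrac >= 0 && lowFrac < highFrac))
        stop("need 0 <= lowFrac < highFrac")
    samp <- colData(cohort)$sample_id
    if (anyNA(samp)) stop("unknown (NA) sample_id in cell metadata")
    if (ncol(cohort) == 0L) return(cohort)
    detected <- Matrix::colSums(assay(cohort, "counts") > 0)
    keep <- logical(ncol(cohort))
    for (s in unique(samp)) {
        i <- samp == s
        m <- mean(detected[i])
        keep[i] <- detected[i] >= lowFrac * m & detected[i] <= highFrac * m
    }
    cohort[, keep]
}

#' Library-size log-normalization
#'
#' `value(c, g) = ln(1 + count(c, g) / total(c) * scaleTotal)`: each cell is
#' scaled to `scaleTotal` total counts and natural-log transformed with a
#' pseudocount of 1. Stored as the `"logcounts"` assay; normalization
#' parameters are recorded in `metadata()$normalization`.
#'
#' @param cohort a [PCPGCohort-class] with a counts assay.
#' @param scaleTotal target total count per cell (default 10000).
#' @return the cohort with a `"logcounts"` assay added.
#' @export
normalizeLog <- function(cohort, scaleTotal = 10000) {
    .assertCohort(cohort)
    m <- assay(cohort, "counts")
    totals <- Matrix::colSums(m)
    if (any(totals == 0)) {
        bad <- colnames(cohort)[totals == 0]
        stop("cell(s) with zero total count: ",
             paste(head(bad, 5), collapse = ", "))
    }
    norm <- m %*% Matrix::Diagonal(x = scaleTotal / totals)
    norm <- methods::as(norm, "CsparseMatrix")
    norm@x <- log1p(norm@x)
    dimnames(norm) <- dimnames(m)
    assay(cohort, "logcounts") <- norm
    metadata(cohort)$normalization <- list(scale_total = scaleTotal,
                                           pseudocount = 1,
                                           log_base = "e")
    cohort
}

#' Highly variable gene selection
#'
#' Ranks genes by a mean-standardized dispersion: the variance of the
#' log-normalized values, z-standardized within `nBins` equal-frequency
#' bins of mean expression (so high-expression genes do not dominate).
#' Genes with zero dispersion (constant in all cells) are ranked last.
#'
#' @param cohort a [PCPGCohort-class] with `"logcounts"` (see
#'   [normalizeLog()]).
#' @param n number of genes to select (default 4000, capped at the number
#'   of genes available).
#' @param nBins number of equal-frequency mean-expression bins (default 20).
#' @param assayName assay to compute the statistic on: `"logcounts"`
#'   (default) or `"counts"` (dispersion on the raw counts).
#' @return data.frame over all genes, sorted by standardized dispersion
#'   descending, with columns `gene`, `mean`, `dispersion`,
#'   `dispersion_std` and a logical `selected` marking the top `n`.
#' @export
selectHVG <- function(cohort, n = 4000, nBins = 20,
                      assayName = c("logcounts", "counts")) {
    .assertCohort(cohort)
    if (n <= 0) stop("n must be positive")
    x <- assay(cohort, match.arg(assayName))
    n <- min(n, nrow(x))
    mu <- Matrix::rowMeans(x)
    ex2 <- Matrix::rowMeans(x^2)
    nc <- ncol(x)
    disp <- (ex2 - mu^2) * nc / max(nc - 1, 1)
    disp[disp < 0] <- 0  # numerical noise
    breaks <- unique(quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
    bin <- cut(mu, breaks = breaks, include.lowest = TRUE)
    z <- disp
    for (b in levels(bin)) {
        i <- bin == b
        s <- sd(disp[i])
        z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
    }
    z[disp == 0] <- -Inf
    out <- data.frame(gene = rownames(x), mean = mu, dispersion = disp,
                      dispersion_std = z, row.names = NULL,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$dispersion_std, out$gene), ]
    out$selected <- seq_len(nrow(out)) <= n
    rownames(out) <- NULL
    out
}

#' Gene-wise scaling (z-scores with clipping)
#'
#' Per gene: subtract the mean and divide by the population standard
#' deviation of the log-normalized values (zero-sd genes map to 0), then
#' clip to `[-clip, clip]` so outlier cells cannot dominate PCA.
#'
#' @param cohort a [PCPGCohort-class] with `"logcounts"`.
#' @param genes character vector of genes to scale (e.g. the HVGs).
#' @param clip symmetric clipping bound (default 10).
#' @return dense cells x genes matrix of scaled values.
#' @export
scaleGenes <- function(cohort, genes, clip = 10) {
    .assertCohort(cohort)
    if (length(genes) == 0L) stop("empty gene list")
    if (!all(genes %in% rownames(cohort)))
        stop("genes not in cohort: ",
             paste(head(setdiff(genes, rownames(cohort)), 5), collapse = ", "))
    m <- t(as.matrix(assay(cohort, "logcounts")[genes, , drop = FALSE]))
    mu <- colMeans(m)
    sdev <- sqrt(colMeans(m^2) - mu^2)
    sdev[sdev < 1e-12] <- Inf  # constant genes -> all zeros
    m <- sweep(sweep(m, 2L, mu, `-`), 2L, sdev, `/`)
    m[m > clip] <- clip
    m[m < -clip] <- -clip
    m
}
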