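#' Center expression on a reference cell population
#'
#' Per gene, subtracts the mean log-normalized expression over the
#' reference cells from every cell (reference cells included — they are
#' centered and carried through, so aberrations in the reference would
#' still be visible), then clamps the result to `[-clamp, clamp]` to bound
#' outliers before genomic smoothing.
#'
#' @param cohort a [PCPGCohort-class] with `"logcounts"`.
#' @param referenceCells character vector of cell ids (or logical/integer
#'   index) defining the reference population; must be non-empty.
#' @param clamp symmetric bound on centered values (default 3).
#' @return dense cells x genes matrix of centered, clamped values.
#' @export
centerOnReference <- function(cohort, referenceCells, clamp = 3) {
    .assertCohort(cohort)
    x <- .cellsByGenes(cohort, "logcounts")
    if (is.character(referenceCells))
        referenceCells <- match(referenceCells, rownames(x))
    ref <- x[referenceCells, , drop = FALSE]
    if (nrow(ref) == 0L) stop("reference cell set is empty")
    centered <- sweep(x, 2L, colMeans(ref), `-`)
    centered[centered > clamp] <- clamp
    centered[centered < -clamp] <- -clamp
    centered
}

# Sparse moving-average operator for one chromosome: row i averages the
# window of `window` genes centered on i, shrunk symmetrically near the
# chromosome ends (half-width min(h, i-1, n-i)).
.smoothOperator <- function(nGenes, window) {
    h <- (window - 1L) %/% 2L
    ii <- jj <- integer(0); xx <- numeric(0)
    for (i in seq_len(nGenes)) {
        hw <- min(h, i - 1L, nGenes - i)
        span <- (i - hw):(i + hw)
        ii <- c(ii, rep(i, length(span)))
        jj <- c(jj, span)
        xx <- c(xx, rep(1 / length(span), length(span)))
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nGenes, nGenes))
}

#' Genomic moving-average smoothing
#'
#' Orders genes canonically (chromosome, start, gene id), then smooths each
#' cell's centered profile with a `window`-gene moving average computed
#' independently per chromosome (never across a chromosome boundary; the
#' window shrinks symmetrically at chromosome ends). Afterwards each cell's
#' median across all genes is subtracted, a robust re-centering that
#' removes cell-level shifts without being pulled by large aberrations.
#'
#' @param centered cells x genes matrix from [centerOnReference()].
#' @param annotation gene-position data.frame (see [readGenePositions()]);
#'   genes absent from it are dropped.
#' @param window odd window size in genes (default 101).
#' @param recenter subtract the per-cell median after smoothing (default
#'   TRUE; disable to inspect raw moving averages).
#' @return cells x genes matrix in canonical genomic order, attribute
#'   `"annotation"` carrying the reordered gene table.
#' @export
smoothGenomic <- function(centered, annotation, window = 101,
                          recenter = TRUE) {
    window <- as.integer(window)
    if (window < 1L || window %% 2L == 0L)
        stop("window must be an odd integer >= 1")
    ann <- annotation[annotation$gene_id %in% colnames(centered), , drop = FALSE]
    ann <- ann[.canonicalGeneOrder(ann), , drop = FALSE]
    rownames(ann) <- NULL
    x <- centered[, ann$gene_id, drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
    for (ch in unique(ann$chromosome)) {
        j <- which(ann$chromosome == ch)
        if (!length(j)) next
        op <- .smoothOperator(length(j), window)
        out[, j] <- as.matrix(x[, j, drop = FALSE] %*% Matrix::t(op))
    }
    if (recenter) {
        med <- apply(out, 1L, median)
        out <- sweep(out, 1L, med, `-`)
    }
    attr(out, "annotation") <- ann
    attr(out, "window") <- window
    out
}

# Viterbi decoding of a 3-state (loss/neutral/gain) Gaussian HMM with state
# means (-delta, 0, +delta), shared emission sd, self-transition pStay and
# symmetric switching. Returns states in {-1, 0, 1}. Uniform initial
# distribution over states.
.viterbi3 <- function(y, delta, sdEmit, pStay) {
    n <- length(y)
    means <- c(-delta, 0, delta)
    logTrans <- matrix(log((1 - pStay) / 2), 3, 3)
    diag(logTrans) <- log(pStay)
    emit <- vapply(means, function(m) dnorm(y, m, sdEmit, log = TRUE),
                   numeric(n))
    emit <- matrix(emit, nrow = n)
    v <- matrix(-Inf, n, 3)
    ptr <- matrix(0L, n, 3)
    v[1, ] <- log(1 / 3) + emit[1, ]
    if (n > 1) for (t in 2:n) {
        for (s in 1:3) {
            cand <- v[t - 1, ] + logTrans[, s]
            ptr[t, s] <- which.max(cand)
            v[t, s] <- cand[ptr[t, s]] + emit[t, s]
        }
    }
    path <- integer(n)
    path[n] <- which.max(v[n, ])
    if (n > 1) for (t in (n - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
    path - 2L
}

#' Three-state copy-number calls per group
#'
#' Averages the smoothed profiles within each group (per-sample tumor
#' populations plus the reference cell types), then segments each group's
#' per-chromosome profile with a three-state Gaussian HMM by Viterbi
#' decoding: state means `(-delta, 0, +delta)`, a shared emission sd
#' estimated as the standard deviation of the smoothed values of the
#' individual reference cells (cell-level, so it reflects the biological
#' and technical variability a group profile can drift by, not just the
#' sampling error of the group mean; a floor of `minSd` guards degenerate
#' references), and symmetric transitions with self-transition probability
#' `pStay`.
#'
#' Before decoding, each group profile is re-centered on its modal value
#' (kernel density peak): the most common dosage state is taken as neutral.
#' The per-cell median re-centering of [smoothGenomic()] is biased when a
#' sizable fraction of the genome is aberrant (the median then sits inside
#' the neutral mass but off its center); anchoring on the mode removes that
#' residual shift without being pulled by the aberrant segments. Profile
#' values within `denoise * sd` of zero are then shrunk to zero — the usual
#' noise-band denoising of expression-CNV practice, which suppresses drift
#' caused by transcriptional (non-dosage) differences between the query
#' and reference cells; set `denoise = 0` to disable.
#'
#' @param smoothed cells x genes matrix from [smoothGenomic()] (canonical
#'   gene order, with its `"annotation"` attribute).
#' @param groups group label per cell (e.g. `"tumor:<sample>"` for
#'   neuroendocrine cells and the cell type for reference cells).
#' @param referenceGroups labels of `groups` treated as reference when
#'   estimating the emission sd.
#' @param delta mean offset of the loss/gain states on the smoothed
#'   log-ratio scale (default 0.15).
#' @param pStay state self-transition probability (default 0.99).
#' @param minCells groups smaller than this are dropped with a warning
#'   (default 10).
#' @param denoise width of the noise band, in units of the reference-cell
#'   sd, shrunk to zero before decoding (default 1.5; 0 disables).
#' @param minSd numerical floor for the emission sd; a reference sd of
#'   exactly zero is an error suggesting a larger reference.
#' @return a [CNVProfile-class].
#' @export
callCNVStates <- function(smoothed, groups, referenceGroups,
                          delta = 0.15, pStay = 0.99, minCells = 10,
                          denoise = 1.5, minSd = 1e-6) {
    ann <- attr(smoothed, "annotation")
    if (is.null(ann)) stop("smoothed must come from smoothGenomic()")
    tab <- table(groups)
    keep <- names(tab)[tab >= minCells]
    if (length(drop <- setdiff(names(tab), keep)))
        warning("dropping group(s) with < ", minCells, " cells: ",
                paste(drop, collapse = ", "))
    prof <- t(vapply(keep, function(g) {
        colMeans(smoothed[groups == g, , drop = FALSE])
    }, numeric(ncol(smoothed))))
    refRows <- intersect(referenceGroups, keep)
    if (!length(refRows)) stop("no reference group with enough cells")
    sdEmit <- sd(as.vector(smoothed[groups %in% refRows, , drop = FALSE]))
    if (is.na(sdEmit) || sdEmit == 0)
        stop("degenerate reference sd (0); use a larger reference")
    sdEmit <- max(sdEmit, minSd)
    for (g in seq_len(nrow(prof))) {
        dens <- stats::density(prof[g, ])
        prof[g, ] <- prof[g, ] - dens$x[which.max(dens$y)]
    }
    if (denoise > 0)
        prof[abs(prof) <= denoise * sdEmit] <- 0
    states <- matrix(0L, nrow(prof), ncol(prof), dimnames = dimnames(prof))
    for (ch in unique(ann$chromosome)) {
        j <- which(ann$chromosome == ch)
        for (g in seq_len(nrow(prof)))
            states[g, j] <- .viterbi3(prof[g, j], delta, sdEmit, pStay)
    }
    methods::new("CNVProfile", smoothed = prof, states = states, genes = ann,
                 params = list(delta = delta, p_stay = pStay,
                               sd_emit = sdEmit, denoise = denoise,
                               window = attr(smoothed, "window"),
                               reference_groups = refRows))
}

#' Arm-level copy-number summary
#'
#' For each group and chromosome arm, the fraction of genes called loss and
#' gain; the arm call is `loss`/`gain` when the respective fraction exceeds
#' 0.5, otherwise `neutral`. Arms absent from the annotation are skipped
#' with a warning.
#'
#' @param profile a [CNVProfile-class].
#' @param arms arms to summarize (default: all arms in the profile's
#'   annotation).
#' @return data.frame with columns `group`, `arm`, `fraction_loss`,
#'   `fraction_gain`, `call`.
#' @export
armSummary <- function(profile, arms = NULL) {
    ann <- profile@genes
    if (is.null(ann$arm)) stop("annotation carries no arm labels")
    have <- unique(ann$arm)
    if (is.null(arms)) arms <- have
    if (length(miss <- setdiff(arms, have))) {
        warning("arm(s) absent from annotation, skipped: ",
                paste(miss, collapse = ", "))
        arms <- intersect(arms, have)
    }
    st <- profile@states
    out <- do.call(rbind, lapply(arms, function(a) {
        j <- which(ann$arm == a)
        fl <- rowMeans(st[, j, drop = FALSE] == -1L)
        fg <- rowMeans(st[, j, drop = FALSE] == 1L)
        data.frame(group = rownames(st), arm = a, fraction_loss = fl,
                   fraction_gain = fg,
                   call = ifelse(fl > 0.5, "loss",
                                 ifelse(fg > 0.5, "gain", "neutral")),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
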