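# Internal helpers shared across modules.

# Derive a child seed from a master seed; kept well inside 32-bit range so
# set.seed() never overflows regardless of the master the caller supplies.
.deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

# Dense cells x genes matrix of an assay (genes x cells on disk/in SCE).
.cellsByGenes <- function(sce, assayName = "logcounts") {
    t(as.matrix(assay(sce, assayName)))
}

.assertCohort <- function(x) {
    if (!methods::is(x, "PCPGCohort"))
        stop("expected a PCPGCohort object")
    invisible(x)
}

# Canonical gene order: chromosome (natural string sort), start, gene_id.
.canonicalGeneOrder <- function(ann) {
    order(ann$chromosome, ann$start, ann$gene_id, method = "radix")
}

# Fast column ranks with average ties, returning a cells x genes matrix of
# ranks computed per gene. Used by the vectorized rank-sum test.
.columnRanks <- function(m) {
    apply(m, 2L, rank, ties.method = "average")
}
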