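mkAnn <- function(n, chrom = "chr1", armSplit = n %/% 2) {
    data.frame(gene_id = sprintf("s%03d", seq_len(n)), chromosome = chrom,
               start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
               arm = rep(paste0(sub("chr", "", chrom), c("p", "q")),
                         c(armSplit, n - armSplit)))
}

test_that("reference centering subtracts the reference mean and clamps", {
    m <- matrix(0L, 1, 4, dimnames = list("g1", sprintf("c%d", 1:4)))
    m[1, ] <- c(7L, 7L, 12L, 90L)
    co <- normalizeLog(toyCohort(m + 1L), scaleTotal = 1)
    centered <- centerOnReference(co, c("c1", "c2"), clamp = 3)
    lam <- t(as.matrix(assay(co, "logcounts")))
    expect_equal(centered["c3", "g1"],
                 lam["c3", "g1"] - mean(lam[c("c1", "c2"), "g1"]))
    expect_equal(centered["c1", "g1"], centered["c2", "g1"])
    expect_error(centerOnReference(co, integer(0)), "empty")
    # clamping bounds an outlier (logcounts set directly)
    co2 <- toyCohort(matrix(1L, 2, 10,
                            dimnames = list(c("g1", "g2"),
                                            sprintf("c%d", 1:10))))
    lam <- matrix(0, 2, 10, dimnames = dimnames(assay(co2, "counts")))
    lam["g1", 10] <- 8   # 8 above the reference mean of 0
    lam["g2", 10] <- -9  # far below
    assay(co2, "logcounts") <- lam
    cen <- centerOnReference(co2, 1:9, clamp = 3)
    expect_equal(unname(cen[10, "g1"]), 3)
    expect_equal(unname(cen[10, "g2"]), -3)
})

test_that("genomic smoothing reproduces hand-computed cases", {
    ann <- mkAnn(101)
    x <- matrix(0, 1, 101, dimnames = list("cell", ann$gene_id))
    x[1, 51] <- 101
    sm <- smoothGenomic(x, ann, window = 101, recenter = FALSE)
    expect_equal(unname(sm[1, 51]), 1.0)  # full window spans all genes
    # edge gene: window shrinks symmetrically to the single gene
    expect_equal(unname(sm[1, 1]), 0)
    # constant input becomes exactly zero after median re-centering
    cst <- matrix(4.2, 2, 101, dimnames = list(c("a", "b"), ann$gene_id))
    smc <- smoothGenomic(cst, ann, window = 101)
    expect_true(all(abs(smc) < 1e-12))
})

test_that("smoothing matches a convolution oracle on a step profile", {
    ann <- mkAnn(200)
    step <- c(rep(-1, 100), rep(1, 100))
    x <- matrix(step, 1, 200, dimnames = list("cell", ann$gene_id))
    sm <- smoothGenomic(x, ann, window = 41, recenter = FALSE)
    oracle <- vapply(seq_len(200), function(i) {
        hw <- min(20, i - 1, 200 - i)
        mean(step[(i - hw):(i + hw)])
    }, numeric(1))
    expect_equal(unname(sm[1, ]), oracle, tolerance = 1e-12)
    # the ramp spans about one window around the boundary
    ramp <- which(abs(sm[1, ]) < 1 - 1e-9)
    expect_lte(length(ramp), 41)
    expect_gte(length(ramp), 39)
})

test_that("smoothing is translation-equivariant before re-centering", {
    ann <- mkAnn(120)
    set.seed(21)
    x <- matrix(rnorm(3 * 120), 3, 120,
                dimnames = list(letters[1:3], ann$gene_id))
    a <- smoothGenomic(x, ann, window = 21, recenter = FALSE)
    b <- smoothGenomic(x + 5, ann, window = 21, recenter = FALSE)
    expect_equal(b, a + 5, tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("smoothing never crosses chromosome boundaries", {
    ann <- rbind(mkAnn(60, "chr1"), mkAnn(60, "chr2"))
    ann$gene_id <- sprintf("s%03d", 1:120)
    x <- matrix(c(rep(0, 60), rep(10, 60)), 1, 120,
                dimnames = list("cell", ann$gene_id))
    sm <- smoothGenomic(x, ann, window = 21, recenter = FALSE)
    expect_equal(unname(sm[1, 60]), 0)   # last chr1 gene untouched
    expect_equal(unname(sm[1, 61]), 10)  # first chr2 gene untouched
    expect_error(smoothGenomic(x, ann, window = 20), "odd")
})

test_that("Viterbi decoding equals exhaustive path enumeration", {
    set.seed(22)
    for (rep in 1:6) {
        n <- sample(5:9, 1)
        truth <- cumsum(sample(c(-1, 0, 1), n, replace = TRUE,
                               prob = c(.15, .7, .15)))
        truth <- pmax(pmin(truth, 1), -1)
        y <- truth * 0.3 + rnorm(n, sd = 0.1)
        v <- pcpgHet:::.viterbi3(y, delta = 0.3, sdEmit = 0.12, pStay = 0.9)
        b <- bruteViterbi(y, delta = 0.3, sdEmit = 0.12, pStay = 0.9)
        expect_identical(v, b)
    }
})

test_that("an all-zero profile is called neutral everywhere", {
    ann <- mkAnn(80)
    sm <- matrix(0, 30, 80,
                 dimnames = list(sprintf("c%d", 1:30), ann$gene_id))
    # tiny reference jitter so the sd is defined
    set.seed(23)
    sm[21:30, ] <- rnorm(800, sd = 1e-3)
    attr(sm, "annotation") <- ann
    groups <- rep(c("tumor", "ref"), c(20, 10))
    prof <- callCNVStates(sm, groups, "ref")
    expect_true(all(cnvStates(prof)["tumor", ] == 0L))
    # degenerate reference sd errors with advice
    sm0 <- matrix(0, 30, 80,
                  dimnames = list(sprintf("c%d", 1:30), ann$gene_id))
    attr(sm0, "annotation") <- ann
    expect_error(callCNVStates(sm0, groups, "ref"), "larger reference")
})

test_that("planted dosage segments are recovered on a small cohort", {
    co <- smallCohort()
    cd <- colData(co)
    isNE <- cd$true_cell_type == "neuroendocrine"
    grp <- ifelse(isNE, paste0("NE:", cd$sample_id), cd$true_cell_type)
    ann <- as.data.frame(rowData(co)); ann$gene_id <- rownames(co)
    sm <- smoothGenomic(centerOnReference(co, which(!isNE)), ann, 101)
    prof <- callCNVStates(sm, grp, c("immune", "stromal", "cortical"))
    st <- cnvStates(prof)
    truth <- truthStates(prof, co)
    tumors <- grep("^NE:", rownames(st), value = TRUE)
    on1p <- prof@genes$arm == "1p"
    # >= 90% of 1p genes called loss in every tumor group
    expect_true(all(rowMeans(st[tumors, on1p] == -1L) >= 0.9))
    # <= 5% of truly neutral genes called non-neutral
    neutral <- truth == 0L
    expect_lte(mean(st[neutral] != 0L), 0.05)
    # reference groups are >= 95% neutral
    refs <- setdiff(rownames(st), tumors)
    expect_gte(mean(st[refs, ] == 0L), 0.95)
})

test_that("arm summary calls arms by majority state", {
    ann <- mkAnn(40)
    st <- matrix(0L, 2, 40, dimnames = list(c("g1", "g2"), ann$gene_id))
    st["g1", ann$arm == "1p"] <- -1L
    sm <- matrix(0, 2, 40, dimnames = dimnames(st))
    prof <- methods::new("CNVProfile", smoothed = sm, states = st,
                         genes = ann, params = list(window = 1))
    out <- armSummary(prof)
    g1p <- out[out$group == "g1" & out$arm == "1p", ]
    expect_equal(g1p$fraction_loss, 1)
    expect_identical(g1p$call, "loss")
    expect_true(all(out$fraction_loss + out$fraction_gain <= 1))
    expect_warning(armSummary(prof, arms = c("1p", "9q")), "9q")
})
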