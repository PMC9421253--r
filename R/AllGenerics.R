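#' Accessors for pcpgHet result classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `programs()` returns the long-format program table of a [ProgramSet-class];
#' `metaprogramGenes()` the frequency-ranked gene table of a
#' [MetaprogramSet-class]; `metaprogramScores()` its per-cell score matrix;
#' `programAssignment()` the program-to-metaprogram map; `cnvStates()` and
#' `cnvSmoothed()` the state and smoothed matrices of a [CNVProfile-class].
#'
#' @param x the object.
#' @return the underlying table or matrix (a copy; never a slot reference
#'   the caller could corrupt).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("programs", function(x) standardGeneric("programs"))
#' @rdname accessors
#' @export
setMethod("programs", "ProgramSet", function(x) x@programs)

#' @rdname accessors
#' @export
setGeneric("metaprogramGenes", function(x) standardGeneric("metaprogramGenes"))
#' @rdname accessors
#' @export
setMethod("metaprogramGenes", "MetaprogramSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("metaprogramScores",
           function(x) standardGeneric("metaprogramScores"))
#' @rdname accessors
#' @export
setMethod("metaprogramScores", "MetaprogramSet", function(x) x@cellScores)

#' @rdname accessors
#' @export
setGeneric("programAssignment",
           function(x) standardGeneric("programAssignment"))
#' @rdname accessors
#' @export
setMethod("programAssignment", "MetaprogramSet", function(x) x@assignment)

#' @rdname accessors
#' @export
setGeneric("cnvStates", function(x) standardGeneric("cnvStates"))
#' @rdname accessors
#' @export
setMethod("cnvStates", "CNVProfile", function(x) x@states)

#' @rdname accessors
#' @export
setGeneric("cnvSmoothed", function(x) standardGeneric("cnvSmoothed"))
#' @rdname accessors
#' @export
setMethod("cnvSmoothed", "CNVProfile", function(x) x@smoothed)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "PCPGCohort",
          function(x) metadata(x)$ground_truth)

setMethod("show", "NMFResult", function(object) {
    cat("NMFResult for sample", object@sampleId, "\n",
        " ", nrow(object@W), "genes x", ncol(object@H), "cells, k =",
        object@k, "\n",
        "  final objective:", format(utils::tail(object@objective, 1)),
        "after", length(object@objective), "iterations\n")
})

setMethod("show", "ProgramSet", function(object) {
    p <- object@programs
    cat("ProgramSet:", length(unique(p$program_id)), "programs from",
        length(unique(p$sample_id)), "sample(s), top", object@topN,
        "genes each\n")
})

setMethod("show", "MetaprogramSet", function(object) {
    cat("MetaprogramSet:", object@nMeta, "metaprograms over",
        length(object@assignment), "programs;",
        nrow(object@cellScores), "cells scored\n")
})

setMethod("show", "CNVProfile", function(object) {
    tab <- table(factor(object@states, levels = c(-1, 0, 1),
                        labels = c("loss", "neutral", "gain")))
    cat("CNVProfile:", nrow(object@smoothed), "group(s) x",
        ncol(object@smoothed), "genes; window =", object@params$window, "\n",
        " state calls:", paste(names(tab), as.integer(tab), sep = "=",
                               collapse = " "), "\n")
})

setMethod("show", "SimilarityModel", function(object) {
    cat("SimilarityModel: ", length(object@types), " reference types, ",
        length(object@genes), " genes, alpha = ", object@alpha, "\n", sep = "")
})

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig:", object@nSamplesRET, "RET +", object@nSamplesSDHB,
        "SDHB samples,", object@cellsPerSample, "cells/sample,",
        object@nGenes, "genes;", object@nSharedPrograms,
        "shared programs of", object@programSize, "genes;",
        nrow(object@cnvSegments), "CNV segment rule(s); seed", object@seed,
        "\n")
})
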