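#' @rdname InteractionDataset-class
#' @aliases lncrnaIds proteinIds adjacency
#' @export
setMethod("lncrnaIds", "InteractionDataset", function(x) x@lncrnaIds)

#' @rdname InteractionDataset-class
#' @export
setMethod("proteinIds", "InteractionDataset", function(x) x@proteinIds)

#' @rdname InteractionDataset-class
#' @export
setMethod("adjacency", "InteractionDataset", function(x) x@adjacency)

#' @rdname InteractionDataset-class
#' @export
setMethod("dim", "InteractionDataset", function(x) dim(x@adjacency))

setMethod("show", "InteractionDataset", function(object) {
    A <- object@adjacency
    cat("InteractionDataset:", nrow(A), "lncRNAs x", ncol(A), "proteins,",
        sum(A), "interactions (density",
        sprintf("%.4f", mean(A)), ")\n")
    invisible(NULL)
})

#' @rdname SimilarityKernel-class
#' @aliases kernelValues kernelAxis kernelSource
#' @export
setMethod("kernelValues", "SimilarityKernel", function(x) x@values)

#' @rdname SimilarityKernel-class
#' @export
setMethod("kernelAxis", "SimilarityKernel", function(x) x@axis)

#' @rdname SimilarityKernel-class
#' @export
setMethod("kernelSource", "SimilarityKernel", function(x) x@source)

#' @rdname SimilarityKernel-class
#' @export
setMethod("dim", "SimilarityKernel", function(x) dim(x@values))

setMethod("show", "SimilarityKernel", function(object) {
    cat("SimilarityKernel [", object@source, "] over ", object@axis,
        " axis: ", nrow(object@values), " x ", ncol(object@values), "\n",
        sep = "")
    if (length(object@scaleGamma))
        cat("  Gaussian bandwidth gamma =",
            format(object@scaleGamma, digits = 6), "\n")
    invisible(NULL)
})

#' @rdname FusionState-class
#' @aliases fusedSimilarity agreementMatrix
#' @export
setMethod("fusedSimilarity", "FusionState", function(x) x@similarity)

#' @rdname FusionState-class
#' @export
setMethod("agreementMatrix", "FusionState", function(x) x@weights)

setMethod("show", "FusionState", function(object) {
    p <- object@params
    cat("FusionState:", length(object@theta), "kernels fused over a",
        nrow(object@similarity), "-entity space\n")
    cat("  alpha =", p$alpha, " k =", p$k, " z =", p$z, "\n")
    invisible(NULL)
})

#' @rdname LpiPrediction-class
#' @aliases predictionScores
#' @export
setMethod("predictionScores", "LpiPrediction", function(x) x@scores)

setMethod("show", "LpiPrediction", function(object) {
    cat("LpiPrediction:", nrow(object@scores), "x", ncol(object@scores),
        "score matrix\n")
    cat("  delta =", object@params$delta,
        " betaL =", object@params$betaL,
        " betaP =", object@params$betaP, "\n")
    invisible(NULL)
})
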