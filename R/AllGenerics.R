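#' @rdname InteractionDataset-class
#' @param object,x an object.
#' @export
setGeneric("lncrnaIds", function(x) standardGeneric("lncrnaIds"))

#' @rdname InteractionDataset-class
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname InteractionDataset-class
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname SimilarityKernel-class
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' @rdname SimilarityKernel-class
#' @export
setGeneric("kernelAxis", function(x) standardGeneric("kernelAxis"))

#' @rdname SimilarityKernel-class
#' @export
setGeneric("kernelSource", function(x) standardGeneric("kernelSource"))

#' @rdname FusionState-class
#' @export
setGeneric("fusedSimilarity", function(x) standardGeneric("fusedSimilarity"))

#' @rdname FusionState-class
#' @export
setGeneric("agreementMatrix", function(x) standardGeneric("agreementMatrix"))

#' @rdname LpiPrediction-class
#' @export
setGeneric("predictionScores",
    function(x) standardGeneric("predictionScores"))
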