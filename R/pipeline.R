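# High-level wrappers assembling the canonical three-kernel set per axis
# and running the fuse + solve pipeline in one call.

#' Build the canonical kernel sets for both axes
#'
#' `lncrnaKernelSet()` returns the three lncRNA kernels — Gaussian
#' interaction-profile, expression correlation, and linear neighborhood
#' similarity over mono-/dinucleotide composition features.
#' `proteinKernelSet()` returns the three protein kernels —
#' interaction-profile, alignment bit-score ratio, and linear neighborhood
#' similarity over CTD features. The feature-based neighbor counts
#' default to `ceiling(n / 10)` for lncRNAs and 3 for proteins.
#'
#' @param dataset an [InteractionDataset].
#' @param expression lncRNA x tissue expression matrix (rows ordered as
#'   `lncrnaIds(dataset)`).
#' @param lncSeqs named RNA sequences of the lncRNAs.
#' @param kLns neighbor count for the feature-based kernel.
#' @return list of three [SimilarityKernel] objects, interaction kernel
#'   first.
#' @export
lncrnaKernelSet <- function(dataset, expression, lncSeqs, kLns = NULL) {
    ord <- lncrnaIds(dataset)
    stopifnot(all(ord %in% rownames(expression)),
              all(ord %in% names(lncSeqs)))
    feats <- lncrnaNucleotideFeatures(lncSeqs)[ord, , drop = FALSE]
    list(
        gipKernel(dataset, "lncrna"),
        expressionSimilarity(expression[ord, , drop = FALSE]),
        lnsSimilarity(feats, k = kLns, axis = "lncrna",
                      symmetrize = TRUE)
    )
}

#' @rdname lncrnaKernelSet
#' @param bitscores protein x protein bit-score matrix; if `NULL` it is
#'   computed from `protSeqs` with [pairwiseBitscores()].
#' @param protSeqs named protein sequences.
#' @export
proteinKernelSet <- function(dataset, bitscores = NULL, protSeqs,
                             kLns = 3L) {
    ord <- proteinIds(dataset)
    if (is.null(bitscores))
        bitscores <- pairwiseBitscores(protSeqs)
    stopifnot(all(ord %in% rownames(bitscores)),
              all(ord %in% names(protSeqs)))
    feats <- proteinCTDFeatures(protSeqs)[ord, , drop = FALSE]
    list(
        gipKernel(dataset, "protein"),
        alignmentSimilarity(bitscores[ord, ord]),
        lnsSimilarity(feats, k = kLns, axis = "protein",
                      symmetrize = TRUE)
    )
}

#' Fuse both kernel sets and score every lncRNA-protein pair
#'
#' Convenience wrapper: fuses the lncRNA and protein kernel lists with
#' their respective fusion parameters and runs the Laplacian regularized
#' least-squares solver on the fused similarities.
#'
#' @param dataset an [InteractionDataset] (supplies the label matrix).
#' @param lncKernels,protKernels kernel lists as from [lncrnaKernelSet()]
#'   and [proteinKernelSet()] (interaction kernel included).
#' @param skfL,skfP [skfParams()] per axis.
#' @param params a [laprlsParams()] bundle.
#' @return list: `prediction` ([LpiPrediction]) plus the two
#'   [FusionState]s (`fusionL`, `fusionP`).
#' @export
lpiPredict <- function(dataset, lncKernels, protKernels, skfL, skfP,
                       params = laprlsParams()) {
    fusionL <- fuseKernels(lncKernels, skfL)
    fusionP <- fuseKernels(protKernels, skfP)
    list(
        prediction = predictBipartite(fusionL, fusionP, dataset, params),
        fusionL = fusionL,
        fusionP = fusionP
    )
}
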