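#' @import methods
NULL

#' InteractionDataset: a bipartite lncRNA-protein interaction network
#'
#' Container for the binary adjacency matrix \eqn{A} of a bipartite
#' interaction network together with the frozen identifier orders of its two
#' axes. Rows index lncRNAs, columns index proteins; \code{A[i, j] = 1}
#' records a known interaction between the i-th lncRNA and the j-th protein,
#' and 0 records an unobserved (not a negative) pair.
#'
#' @slot lncrnaIds character vector of unique lncRNA identifiers (row order).
#' @slot proteinIds character vector of unique protein identifiers
#'   (column order).
#' @slot adjacency numeric matrix with entries in \{0, 1\}, dimension
#'   \code{length(lncrnaIds) x length(proteinIds)}.
#'
#' @seealso [buildAdjacency()] to construct one from a pair list,
#'   [gipKernel()] for the interaction-profile kernels derived from it.
#' @exportClass InteractionDataset
setClass("InteractionDataset",
    representation(
        lncrnaIds = "character",
        proteinIds = "character",
        adjacency = "matrix"
    )
)

setValidity("InteractionDataset", function(object) {
    msg <- character()
    A <- object@adjacency
    if (length(object@lncrnaIds) < 1L || length(object@proteinIds) < 1L)
        msg <- c(msg, "both axes must hold at least one identifier")
    if (anyDuplicated(object@lncrnaIds))
        msg <- c(msg, "duplicated lncRNA identifiers")
    if (anyDuplicated(object@proteinIds))
        msg <- c(msg, "duplicated protein identifiers")
    if (nrow(A) != length(object@lncrnaIds) ||
        ncol(A) != length(object@proteinIds))
        msg <- c(msg, "adjacency dimension does not match identifier lists")
    if (!all(A %in% c(0, 1)))
        msg <- c(msg, "adjacency entries must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' SimilarityKernel: a square similarity matrix over one molecular space
#'
#' A nonnegative square matrix of pairwise similarities over either the
#' lncRNA or the protein axis of an [InteractionDataset], tagged with the
#' source that produced it. The three canonical sources per axis are the
#' Gaussian interaction-profile kernel (\code{"interaction"}), the
#' expression-correlation (lncRNA) or alignment bit-score ratio (protein)
#' kernel, and the linear-neighborhood kernel over sequence statistical
#' features (\code{"statfeat"}).
#'
#' @slot values square numeric matrix; rows/columns follow the axis's frozen
#'   identifier order (dimnames carry the identifiers).
#' @slot axis \code{"lncrna"} or \code{"protein"}.
#' @slot source short tag naming the similarity source, e.g.
#'   \code{"interaction"}, \code{"expression"}, \code{"alignment"},
#'   \code{"statfeat"}, \code{"fused"}.
#' @slot scaleGamma numeric; the Gaussian bandwidth used by an
#'   interaction-profile kernel (length 0 for other sources).
#'
#' @exportClass SimilarityKernel
setClass("SimilarityKernel",
    representation(
        values = "matrix",
        axis = "character",
        source = "character",
        scaleGamma = "numeric"
    ),
    prototype(scaleGamma = numeric(0))
)

setValidity("SimilarityKernel", function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v))
        msg <- c(msg, "kernel matrix must be square")
    if (!all(is.finite(v)))
        msg <- c(msg, "kernel entries must be finite")
    else if (any(v < 0))
        msg <- c(msg, "kernel entries must be nonnegative")
    if (length(object@axis) != 1L ||
        !object@axis %in% c("lncrna", "protein"))
        msg <- c(msg, "axis must be 'lncrna' or 'protein'")
    if (length(object@source) != 1L)
        msg <- c(msg, "source must be a single string")
    if (length(msg)) msg else TRUE
})

#' FusionState: intermediate artifacts of similarity kernel fusion
#'
#' Everything the fusion procedure computes on the way from three input
#' kernels to the adjusted similarity: the column-normalized kernels, the
#' k-nearest-neighbor indicator matrices, the neighbor-normalized kernels,
#' the per-round diffused kernels' average, the neighborhood agreement
#' weights, and the final weighted similarity.
#'
#' @slot theta list of column-normalized kernel matrices (one per source).
#' @slot phi list of row-stochastic neighbor-normalized matrices.
#' @slot indicators list of 0/1 kNN indicator matrices.
#' @slot thetaBar average of the diffused kernels after the final round.
#' @slot weights agreement-weight matrix with entries in \{0, 0.5, 1\}.
#' @slot similarity final adjusted similarity
#'   (\code{thetaBar * weights}, entrywise).
#' @slot params list with elements \code{alpha}, \code{k}, \code{z}.
#'
#' @exportClass FusionState
setClass("FusionState",
    representation(
        theta = "list",
        phi = "list",
        indicators = "list",
        thetaBar = "matrix",
        weights = "matrix",
        similarity = "matrix",
        params = "list"
    )
)

#' LpiPrediction: bipartite interaction score matrices
#'
#' Scores for every lncRNA-protein pair, as produced by Laplacian
#' regularized least squares on the two fused similarity spaces and their
#' convex combination.
#'
#' @slot scores final n x m score matrix \eqn{F}.
#' @slot scoresLnc score matrix from the lncRNA-space solve.
#' @slot scoresProt score matrix from the protein-space solve (already
#'   transposed back to n x m).
#' @slot params list with \code{betaL}, \code{betaP}, \code{delta}.
#'
#' @exportClass LpiPrediction
setClass("LpiPrediction",
    representation(
        scores = "matrix",
        scoresLnc = "matrix",
        scoresProt = "matrix",
        params = "list"
    )
)

setValidity("LpiPrediction", function(object) {
    if (!all(is.finite(object@scores)))
        return("scores must be finite")
    if (!identical(dim(object@scores), dim(object@scoresLnc)) ||
        !identical(dim(object@scores), dim(object@scoresProt)))
        return("score matrices must share one shape")
    TRUE
})
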