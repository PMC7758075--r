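# Similarity kernel fusion: iterative cross-diffusion of normalized
# kernels through the neighbor-restricted versions of the others, followed
# by averaging and masking by neighborhood agreement.

#' Column-normalize a similarity kernel
#'
#' Divides every entry by its column sum, so each column of the result
#' sums to one. An all-zero column is an error (that entity has zero
#' similarity from everyone under this kernel; no silent epsilon is
#' applied).
#'
#' @param s a [SimilarityKernel] or square matrix.
#' @return a column-stochastic matrix.
#' @export
columnNormalize <- function(s) {
    S <- asKernelMatrix(s)
    cs <- colSums(S)
    if (any(cs == 0)) {
        who <- colnames(S)[cs == 0]
        if (is.null(who)) who <- which(cs == 0)
        stop("all-zero similarity column for entity: ",
             paste(who, collapse = ", "))
    }
    sweep(S, 2, cs, "/")
}

#' k-nearest-neighbor indicator matrix
#'
#' `I[u, v] = 1` exactly when v is among the k entities most similar to u
#' under `s`, with self excluded from every neighborhood. Ties are broken
#' deterministically by lower index after sorting by decreasing
#' similarity. Every row sums to exactly k.
#'
#' @param s a [SimilarityKernel] or square matrix.
#' @param k neighborhood size, `1 <= k < nrow(s)`.
#' @return a 0/1 matrix with zero diagonal and row sums k.
#' @export
knnIndicator <- function(s, k) {
    S <- asKernelMatrix(s)
    n <- nrow(S)
    k <- as.integer(k)
    if (k >= n) stop("k must be smaller than the number of entities")
    if (k < 1L) stop("k must be at least 1")
    I <- matrix(0, n, n, dimnames = dimnames(S))
    for (u in seq_len(n)) {
        others <- setdiff(seq_len(n), u)
        nb <- others[order(-S[u, others], others)][seq_len(k)]
        I[u, nb] <- 1
    }
    I
}

#' Neighbor-constrained normalization
#'
#' Restricts a kernel to each row's k-nearest-neighbor set and
#' renormalizes the surviving entries to sum to one per row:
#' `Phi[u, v] = s[u, v] I[u, v] / sum_t s[u, t] I[u, t]`. Rows whose
#' retained neighbors all have similarity zero are an error (the kernel is
#' degenerate at that entity).
#'
#' @param s a [SimilarityKernel] or square matrix.
#' @param I a 0/1 indicator matrix as from [knnIndicator()].
#' @return a row-stochastic matrix supported on the neighborhoods.
#' @export
neighborNormalize <- function(s, I) {
    S <- asKernelMatrix(s)
    if (!identical(dim(S), dim(I))) stop("dimension mismatch")
    M <- S * I
    rs <- rowSums(M)
    if (any(rs == 0)) {
        who <- rownames(S)[rs == 0]
        if (is.null(who)) who <- which(rs == 0)
        stop("zero similarity over the whole neighborhood of: ",
             paste(who, collapse = ", "))
    }
    sweep(M, 1, rs, "/")
}

#' Iterative cross-diffusion of normalized kernels
#'
#' Runs the fusion iteration: each kernel is updated synchronously as
#' \deqn{\Theta_q(\lambda+1) = \tfrac{\alpha}{2}\,\Phi_q
#'   \big(\sum_{r \ne q} \Theta_r(\lambda)\big) \Phi_q^T +
#'   \tfrac{1-\alpha}{2} \sum_{r \ne q} \Theta_r(0),}
#' where the 1/2 averages over the other two kernels (with K kernels the
#' factor becomes 1/(K-1)). After `z` rounds the diffused kernels are
#' averaged into the fused matrix. `z = 0` returns the plain average of
#' the inputs.
#'
#' @param theta list of column-normalized kernels (round-0 matrices).
#' @param phi list of row-stochastic neighbor-normalized kernels, same
#'   length and dimensions.
#' @param params an [skfParams()] bundle (`alpha`, `z` used here).
#' @param renormalize re-column-normalize each kernel after every round
#'   (off by default; the canonical iteration applies none).
#' @return the fused matrix, the entrywise mean of the round-z kernels.
#' @export
skfDiffuse <- function(theta, phi, params, renormalize = FALSE) {
    K <- length(theta)
    stopifnot(K >= 2L, length(phi) == K)
    dims <- vapply(c(theta, phi), nrow, 1L)
    if (length(unique(dims)) != 1L) stop("kernel dimension mismatch")
    alpha <- params$alpha
    z <- params$z
    theta0 <- theta
    sum0 <- Reduce(`+`, theta0)
    cur <- theta0
    if (z > 0) for (round in seq_len(z)) {
        sumCur <- Reduce(`+`, cur)
        nxt <- vector("list", K)
        for (q in seq_len(K)) {
            restLambda <- sumCur - cur[[q]]
            rest0 <- sum0 - theta0[[q]]
            nxt[[q]] <- (alpha / (K - 1)) *
                (phi[[q]] %*% restLambda %*% t(phi[[q]])) +
                ((1 - alpha) / (K - 1)) * rest0
        }
        if (renormalize)
            nxt <- lapply(nxt, columnNormalize)
        cur <- nxt
    }
    Reduce(`+`, cur) / K
}

#' Neighborhood agreement weights
#'
#' For each ordered pair (u, v), 1 if v is a k-nearest neighbor of u under
#' all kernels, 0 if under none, and 0.5 otherwise. The resulting
#' \{0, 0.5, 1\} matrix masks the fused kernel, suppressing similarity
#' mass on pairs the individual kernels disagree about.
#'
#' @param indicators list of 0/1 indicator matrices from [knnIndicator()].
#' @return a matrix with entries in \{0, 0.5, 1\}.
#' @export
agreementWeights <- function(indicators) {
    stopifnot(length(indicators) >= 2L)
    tot <- Reduce(`+`, indicators)
    K <- length(indicators)
    W <- matrix(0.5, nrow(tot), ncol(tot), dimnames = dimnames(tot))
    W[tot == K] <- 1
    W[tot == 0] <- 0
    W
}

#' Fuse similarity kernels into one adjusted similarity
#'
#' The full fusion pipeline over one molecular space: column-normalize
#' each kernel, build its k-nearest-neighbor indicator and
#' neighbor-normalized version, run `z` rounds of cross-diffusion, average
#' the diffused kernels, and mask the average entrywise by the
#' neighborhood agreement weights. Kernels that are asymmetric (alignment
#' ratios, linear-neighborhood weights) are fused as-is; any
#' symmetrization is deferred to the downstream solver.
#'
#' @param kernels list of (typically three) [SimilarityKernel] objects or
#'   square matrices over the same axis and entity order.
#' @param params an [skfParams()] bundle.
#' @return a [FusionState]; the adjusted similarity is in
#'   `fusedSimilarity(state)`.
#' @examples
#' A <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
#' g <- gipKernel(A, "lncrna")
#' st <- fuseKernels(list(g, g, g), skfParams(0.9, k = 1, z = 2))
#' fusedSimilarity(st)
#' @export
fuseKernels <- function(kernels, params) {
    mats <- lapply(kernels, asKernelMatrix)
    axes <- vapply(kernels, function(x)
        if (is(x, "SimilarityKernel")) x@axis else NA_character_,
        character(1))
    axis <- unique(axes[!is.na(axes)])
    if (length(axis) > 1L) stop("kernels span different axes")
    dims <- vapply(mats, nrow, 1L)
    if (length(unique(dims)) != 1L) stop("kernel dimension mismatch")
    theta <- lapply(mats, columnNormalize)
    ind <- lapply(mats, knnIndicator, k = params$k)
    phi <- Map(neighborNormalize, mats, ind)
    thetaBar <- skfDiffuse(theta, phi, params)
    W <- agreementWeights(ind)
    S <- thetaBar * W
    new("FusionState", theta = theta, phi = phi, indicators = ind,
        thetaBar = thetaBar, weights = W, similarity = S,
        params = params)
}
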