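# Laplacian regularized least squares on a fused similarity graph.

#' Normalized graph Laplacian of a similarity matrix
#'
#' Symmetrizes the similarity as `(S + t(S)) / 2` (fused kernels may be
#' asymmetric through the alignment and linear-neighborhood sources, while
#' Laplacian theory and the positive-semidefiniteness guarantee require
#' symmetry), forms the degree diagonal `D = diag(rowSums(S))`, and
#' returns \eqn{L = D^{-1/2} (D - S) D^{-1/2}}. The result is symmetric
#' with eigenvalues in \[0, 2\].
#'
#' @param s a [SimilarityKernel] or square matrix.
#' @param symmetrize symmetrize before normalizing (default TRUE).
#' @return the normalized Laplacian matrix.
#' @export
normalizedLaplacian <- function(s, symmetrize = TRUE) {
    S <- asKernelMatrix(s)
    if (symmetrize) S <- (S + t(S)) / 2
    d <- rowSums(S)
    if (any(d <= 0)) {
        who <- rownames(S)[d <= 0]
        if (is.null(who)) who <- which(d <= 0)
        stop("zero similarity degree for entity: ",
             paste(who, collapse = ", "))
    }
    inv <- 1 / sqrt(d)
    L <- (diag(d) - S) * outer(inv, inv)
    (L + t(L)) / 2
}

#' Closed-form Laplacian regularized least-squares solve (one space)
#'
#' Minimizes \eqn{\|A - F\|_F^2 + \beta\, \mathrm{tr}(F^T L F)} over the
#' similarity graph, whose closed-form minimizer is
#' \eqn{F = S (S + \beta L S)^{-1} A}; for invertible S this equals
#' \eqn{(I + \beta L)^{-1} A}. The system is solved by factorization; if
#' it is numerically singular (reciprocal condition below `rcondTol`) a
#' pseudo-inverse is used instead, with a message reporting the condition
#' estimate.
#'
#' @param s the (fused) similarity over this axis, a [SimilarityKernel] or
#'   matrix.
#' @param L the matching normalized Laplacian from [normalizedLaplacian()].
#' @param A the label matrix for this axis (entities in rows).
#' @param beta positive regularization weight; `beta = 0` returns `A`
#'   when S is invertible.
#' @param rcondTol reciprocal-condition threshold for the pseudo-inverse
#'   fallback.
#' @return the score matrix for this axis, same shape as `A`.
#' @export
laprlsSolve <- function(s, L, A, beta, rcondTol = 1e-12) {
    S <- asKernelMatrix(s)
    A <- as.matrix(A)
    stopifnot(nrow(S) == nrow(A), identical(dim(S), dim(L)))
    if (beta == 0) return(A)   # regularizer off: the fit term alone is
                               # minimized exactly by A itself
    M <- S + beta * (L %*% S)
    rc <- tryCatch(rcond(M), error = function(e) 0)
    if (!is.finite(rc) || rc < rcondTol) {
        message("near-singular LapRLS system (rcond = ",
                format(rc, digits = 3), "); using pseudo-inverse")
        return(S %*% (MASS::ginv(M) %*% A))
    }
    S %*% solve(M, A)
}

#' Score all lncRNA-protein pairs from the two fused similarity spaces
#'
#' Solves the Laplacian regularized least-squares problem independently in
#' the lncRNA space (labels = rows of the adjacency matrix) and in the
#' protein space (labels = columns, i.e. the solve is applied to the
#' transposed adjacency and transposed back), then combines the two score
#' matrices convexly: \eqn{F = \delta F_l + (1 - \delta) F_p}.
#'
#' @param fusedL,fusedP fused similarities over the lncRNA and protein
#'   axes ([SimilarityKernel], [FusionState] or matrix).
#' @param dataset an [InteractionDataset] (or bare adjacency matrix).
#' @param params a [laprlsParams()] bundle.
#' @param symmetrize passed to [normalizedLaplacian()].
#' @return an [LpiPrediction].
#' @export
predictBipartite <- function(fusedL, fusedP, dataset,
                             params = laprlsParams(),
                             symmetrize = TRUE) {
    pick <- function(x) {
        if (is(x, "FusionState")) x@similarity else asKernelMatrix(x)
    }
    SL <- pick(fusedL)
    SP <- pick(fusedP)
    A <- if (is(dataset, "InteractionDataset")) dataset@adjacency
         else as.matrix(dataset)
    stopifnot(nrow(SL) == nrow(A), nrow(SP) == ncol(A))
    LL <- normalizedLaplacian(SL, symmetrize)
    LP <- normalizedLaplacian(SP, symmetrize)
    Fl <- laprlsSolve(SL, LL, A, params$betaL)
    Fp <- t(laprlsSolve(SP, LP, t(A), params$betaP))
    Fm <- params$delta * Fl + (1 - params$delta) * Fp
    dimnames(Fm) <- dimnames(Fl) <- dimnames(Fp) <- dimnames(A)
    new("LpiPrediction", scores = Fm, scoresLnc = Fl, scoresProt = Fp,
        params = params)
}
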