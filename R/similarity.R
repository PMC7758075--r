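# The six similarity kernels: interaction-profile (Gaussian), expression
# correlation, alignment bit-score ratio, and linear neighborhood
# similarity over sequence statistical features.

#' Gaussian interaction-profile kernel
#'
#' Similarity of two entities as a Gaussian of the Euclidean distance
#' between their interaction profiles (rows of the adjacency matrix for
#' lncRNAs, columns for proteins). The bandwidth is set from the data:
#' \eqn{\gamma = n / \sum_i \|A_{i\cdot}\|^2} on the lncRNA axis (the
#' protein axis uses columns and m), so the average squared profile norm
#' is mapped to unit scale.
#'
#' @param dataset an [InteractionDataset], or a bare 0/1 matrix.
#' @param axis `"lncrna"` (rows) or `"protein"` (columns).
#' @return a [SimilarityKernel] with source `"interaction"`; the bandwidth
#'   is stored in its `scaleGamma` slot.
#' @examples
#' ds <- buildAdjacency(cbind(c("L1", "L2"), c("P1", "P2")))
#' kernelValues(gipKernel(ds, "lncrna"))
#' @export
gipKernel <- function(dataset, axis = c("lncrna", "protein")) {
    axis <- match.arg(axis)
    A <- if (is(dataset, "InteractionDataset")) dataset@adjacency
         else as.matrix(dataset)
    P <- if (axis == "lncrna") A else t(A)
    norms2 <- rowSums(P^2)
    if (sum(norms2) == 0)
        stop("GIP scale undefined (division by zero): ",
             "adjacency is all-zero")
    gamma <- nrow(P) / sum(norms2)
    G <- P %*% t(P)
    d2 <- outer(norms2, norms2, "+") - 2 * G
    d2[d2 < 0] <- 0
    S <- exp(-gamma * d2)
    diag(S) <- 1
    ids <- rownames(P)
    if (!is.null(ids)) dimnames(S) <- list(ids, ids)
    new("SimilarityKernel", values = S, axis = axis,
        source = "interaction", scaleGamma = gamma)
}

#' Expression-correlation kernel for lncRNAs
#'
#' Off-diagonal similarity \eqn{(1 + \rho_{u,v}) / 2} where \eqn{\rho} is
#' the Pearson correlation of the two expression profiles, mapping the
#' correlation range \[-1, 1\] onto \[0, 1\]. The diagonal is 0 by
#' convention. Profiles with zero variance (Pearson undefined) and
#' profiles flagged as zero-imputed by [readExpressionTable()] get
#' similarity 0 to all partners, with a warning.
#'
#' @param profiles numeric matrix, lncRNA x tissue (>= 2 columns), as from
#'   [readExpressionTable()].
#' @return a [SimilarityKernel] over the lncRNA axis, source
#'   `"expression"`.
#' @export
expressionSimilarity <- function(profiles) {
    profiles <- as.matrix(profiles)
    if (ncol(profiles) < 2L)
        stop("need >= 2 expression dimensions for a correlation")
    sds <- apply(profiles, 1, stats::sd)
    flat <- sds == 0 | rownames(profiles) %in%
        attr(profiles, "zeroImputed")
    S <- matrix(0, nrow(profiles), nrow(profiles),
                dimnames = list(rownames(profiles), rownames(profiles)))
    ok <- which(!flat)
    if (length(ok) >= 2L) {
        rho <- stats::cor(t(profiles[ok, , drop = FALSE]))
        S[ok, ok] <- (1 + rho) / 2
    }
    if (any(flat))
        warning("zero-variance expression profile(s), similarity set ",
                "to 0: ",
                paste(rownames(profiles)[flat], collapse = ", "))
    diag(S) <- 0
    new("SimilarityKernel", values = S, axis = "lncrna",
        source = "expression")
}

#' Alignment bit-score ratio kernel for proteins
#'
#' Off-diagonal similarity \eqn{b_{u,v} / b_{u,u}}: the bit score of
#' aligning protein u against protein v, normalized by u's self-alignment
#' score. The result is deliberately not symmetrized — the ratio of u
#' against v differs from v against u. Diagonal 0 by convention; ratios
#' above 1 (a cross-alignment outscoring the self-alignment, possible with
#' repeat-rich sequences) are clipped to 1 with a warning.
#'
#' @param b square bit-score matrix with strictly positive diagonal, as
#'   from [readBitscoreTable()] or [pairwiseBitscores()].
#' @return a [SimilarityKernel] over the protein axis, source
#'   `"alignment"`.
#' @export
alignmentSimilarity <- function(b) {
    b <- as.matrix(b)
    if (nrow(b) != ncol(b)) stop("bit-score matrix must be square")
    selfScores <- diag(b)
    if (any(selfScores <= 0))
        stop("nonpositive self bit score for protein(s): ",
             paste(rownames(b)[selfScores <= 0], collapse = ", "))
    S <- b / selfScores          # divides each row u by b[u,u]
    if (any(S > 1 + 1e-12)) {
        warning("bit-score ratio(s) > 1 clipped to 1")
        S[S > 1] <- 1
    }
    diag(S) <- 0
    new("SimilarityKernel", values = S, axis = "protein",
        source = "alignment")
}

# Ungapped Karlin-Altschul parameters for BLOSUM62.
KA_LAMBDA <- 0.3176
KA_K <- 0.134

#' Pairwise local-alignment bit scores
#'
#' Computes a dense bit-score matrix by Smith-Waterman local alignment of
#' every ordered protein pair, as an in-process alternative to running an
#' external alignment search tool and parsing its tabular output. Raw
#' alignment scores (BLOSUM62, gap open 11 / extend 1 by default, via
#' `Biostrings::pairwiseAlignment`) are converted to bit scores with the
#' ungapped Karlin-Altschul constants
#' \eqn{b = (\lambda S_{raw} - \ln K) / \ln 2}. Raw scores are floored at
#' zero (an empty local alignment), so the minimum bit score is
#' \eqn{-\ln K / \ln 2}.
#'
#' @param seqs named protein sequences (`AAStringSet` or named character).
#' @param substitutionMatrix substitution matrix name (default
#'   `"BLOSUM62"`).
#' @param gapOpening,gapExtension gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul scale constants for the bit conversion.
#' @return square numeric bit-score matrix (asymmetry only via rounding;
#'   raw Smith-Waterman scores are symmetric, both triangles are filled
#'   from one alignment).
#' @export
pairwiseBitscores <- function(seqs, substitutionMatrix = "BLOSUM62",
                              gapOpening = 11, gapExtension = 1,
                              lambda = KA_LAMBDA, K = KA_K) {
    x <- seqsAsCharacter(seqs)
    if (any(nchar(x) == 0L)) stop("empty protein sequence")
    n <- length(x)
    subMat <- get(data(list = substitutionMatrix,
                       package = "Biostrings",
                       envir = environment()))
    raw <- matrix(0, n, n, dimnames = list(names(x), names(x)))
    aa <- Biostrings::AAStringSet(x)
    for (u in seq_len(n)) for (v in u:n) {
        sc <- Biostrings::pairwiseAlignment(
            aa[[u]], aa[[v]], type = "local",
            substitutionMatrix = subMat,
            gapOpening = gapOpening, gapExtension = gapExtension,
            scoreOnly = TRUE)
        raw[u, v] <- raw[v, u] <- max(0, sc)
    }
    (lambda * raw - log(K)) / log(2)
}

# Minimize w' G w - 2 c' w  subject to  sum(w) = 1, w >= 0, by a primal
# active-set method: solve the equality-constrained KKT system over the
# free set, fix the most negative weight at zero until feasible, then
# re-free any fixed index whose bound multiplier is negative.
solveSimplexQP <- function(G, c0, tol = 1e-10) {
    k <- nrow(G)
    free <- rep(TRUE, k)
    solveEq <- function(free) {
        f <- which(free)
        kk <- length(f)
        M <- rbind(cbind(2 * G[f, f, drop = FALSE], rep(1, kk)),
                   c(rep(1, kk), 0))
        rhs <- c(2 * c0[f], 1)
        sol <- tryCatch(solve(M, rhs),
                        error = function(e) MASS::ginv(M) %*% rhs)
        w <- numeric(k)
        w[f] <- sol[seq_len(kk)]
        list(w = w, mu = sol[kk + 1L])
    }
    for (iter in seq_len(10L * k + 10L)) {
        sol <- solveEq(free)
        w <- sol$w
        neg <- which(free & w < -tol)
        if (length(neg)) {
            free[neg[which.min(w[neg])]] <- FALSE
            if (!any(free)) break
            next
        }
        w[w < 0] <- 0
        grad <- 2 * as.vector(G %*% w) - 2 * c0 + sol$mu
        viol <- which(!free & grad < -tol)
        if (!length(viol)) return(w)
        free[viol[which.min(grad[viol])]] <- TRUE
    }
    # fallback: clamp and renormalize (degenerate cycling guard)
    w[w < 0] <- 0
    if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
}

#' Linear neighborhood similarity
#'
#' Similarity defined by optimal convex reconstruction weights: each
#' entity's feature vector is approximated as a convex combination of its
#' k nearest neighbors (Euclidean distance, self excluded), minimizing the
#' squared reconstruction error subject to the weights summing to one and
#' being nonnegative. `s(u, v)` is the weight of neighbor v in u's
#' reconstruction and 0 outside the neighborhood, so every row sums to 1,
#' the diagonal is 0, and the matrix is generally asymmetric. The neighbor
#' Gram matrix is ridge-stabilized by `ridge * trace` to keep the
#' quadratic program strictly convex when neighbors are collinear.
#'
#' With `symmetrize = TRUE` the weight matrix is averaged with its
#' transpose before being returned. The raw weight matrix can have
#' all-zero columns (an entity that carries no weight in anyone's
#' reconstruction), which leaves the column normalization of the fusion
#' step undefined; the symmetrized kernel cannot, because every row of
#' the raw weights sums to one. The pipeline wrappers therefore fuse the
#' symmetrized form.
#'
#' @param features numeric matrix, entity x feature, as from
#'   [lncrnaNucleotideFeatures()] or [proteinCTDFeatures()].
#' @param k neighbor count, `1 <= k < nrow(features)`; default
#'   `ceiling(n / 10)`.
#' @param axis axis tag for the returned kernel.
#' @param ridge relative ridge added to the neighbor Gram matrix.
#' @param symmetrize return `(W + t(W)) / 2` instead of the raw
#'   row-stochastic weights.
#' @return a [SimilarityKernel] with source `"statfeat"`.
#' @export
lnsSimilarity <- function(features, k = NULL,
                          axis = c("lncrna", "protein"),
                          ridge = 1e-6, symmetrize = FALSE) {
    axis <- match.arg(axis)
    X <- as.matrix(features)
    n <- nrow(X)
    if (is.null(k)) k <- ceiling(n / 10)
    k <- as.integer(k)
    if (k < 1L || k >= n)
        stop("k must satisfy 1 <= k < number of entities (", n, ")")
    if (!all(is.finite(X))) stop("features must be finite")
    S <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
    d2 <- as.matrix(stats::dist(X))^2
    for (u in seq_len(n)) {
        others <- setdiff(seq_len(n), u)
        nb <- others[order(d2[u, others], others)][seq_len(k)]
        Xn <- X[nb, , drop = FALSE]
        G <- Xn %*% t(Xn)
        tr <- sum(diag(G))
        G <- G + (if (tr > 0) ridge * tr else ridge) * diag(k)
        c0 <- as.vector(Xn %*% X[u, ])
        S[u, nb] <- solveSimplexQP(G, c0)
    }
    S[S < 0] <- 0
    S[S > 1] <- 1
    if (symmetrize) S <- (S + t(S)) / 2
    new("SimilarityKernel", values = S, axis = axis, source = "statfeat")
}
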