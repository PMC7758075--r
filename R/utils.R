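# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user code.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# Accept either a SimilarityKernel or a bare matrix wherever a kernel is
# consumed; keeps the matrix algebra free of class plumbing.
asKernelMatrix <- function(s) {
    if (is(s, "SimilarityKernel")) s@values
    else if (is.matrix(s)) s
    else stop("expected a SimilarityKernel or a matrix")
}

# Balanced fold sizes: n elements into n_folds parts differing by <= 1.
foldSizes <- function(n, nFolds) {
    base <- n %/% nFolds
    sizes <- rep(base, nFolds)
    extra <- n %% nFolds
    if (extra > 0) sizes[seq_len(extra)] <- base + 1L
    sizes
}

#' Parameter bundles for fusion and the regularized solver
#'
#' `skfParams()` collects the three tunables of similarity kernel fusion:
#' the diffusion weight `alpha` in (0,1), the neighborhood size `k`, and
#' the iteration count `z`. `laprlsParams()` collects the two graph
#' regularization weights and the convex combination weight of the two
#' per-space score matrices. Defaults are the calibrated values for the
#' benchmark-scale network (990 lncRNAs, 27 proteins): alpha 0.9 (lncRNA) /
#' 0.8 (protein), k 99 / 3, z = 5, betaL = betaP = 2^-3, delta = 0.8.
#'
#' @param alpha diffusion weight, strictly between 0 and 1.
#' @param k number of nearest neighbors, at least 1 and smaller than the
#'   number of entities on the axis.
#' @param z number of diffusion rounds (z = 0 returns the plain average of
#'   the normalized kernels).
#' @return a named list.
#' @examples
#' skfParams(alpha = 0.9, k = 99, z = 5)
#' laprlsParams()
#' @export
skfParams <- function(alpha, k, z = 5L) {
    stopifnot(is.numeric(alpha), length(alpha) == 1L,
              alpha > 0, alpha < 1)
    k <- as.integer(k)
    z <- as.integer(z)
    stopifnot(k >= 1L, z >= 0L)
    list(alpha = alpha, k = k, z = z)
}

#' @rdname skfParams
#' @param betaL,betaP positive regularization weights for the lncRNA- and
#'   protein-space solves.
#' @param delta weight of the lncRNA-space scores in the final combination,
#'   strictly between 0 and 1.
#' @export
laprlsParams <- function(betaL = 2^-3, betaP = 2^-3, delta = 0.8) {
    stopifnot(betaL > 0, betaP > 0, delta > 0, delta < 1)
    list(betaL = betaL, betaP = betaP, delta = delta)
}

#' Read and write identifier-labelled matrices as TSV
#'
#' All square and rectangular matrices the package emits (kernels, score
#' matrices, adjacency) are serialized as tab-separated tables with the
#' row identifiers in the first column and the column identifiers in the
#' header, at full double precision so a write/read round trip is
#' bit-exact.
#'
#' @param m a numeric matrix with dimnames.
#' @param path file path.
#' @return `readMatrixTSV` returns the matrix; `writeMatrixTSV` returns
#'   `path` invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
    stopifnot(is.matrix(m))
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
    header <- paste(c("id", colnames(m)), collapse = "\t")
    body <- vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i],
                formatC(m[i, ], format = "g", digits = 17)),
              collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
    invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
}
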