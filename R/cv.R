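# Cross-validation with per-fold recomputation of the adjacency-derived
# kernels, so no test information leaks into training.

#' Mask one fold's test information out of the adjacency matrix
#'
#' For the pairwise scheme, the fold's positive cells are set to 0; for
#' the novel-entity schemes the held-out entities' whole rows (lncRNAs) or
#' columns (proteins) are zeroed. The returned matrix is what every
#' adjacency-derived quantity (the interaction-profile kernels, the label
#' matrix of the solver) must be computed from during that fold.
#'
#' @param dataset an [InteractionDataset] or 0/1 matrix.
#' @param plan a fold plan from [pairFolds()] or [entityFolds()].
#' @param fold which fold to hold out.
#' @return list: `trainA` (masked adjacency) and `testCells` (index matrix
#'   of the cells whose scores are evaluated in this fold).
#' @export
maskFold <- function(dataset, plan, fold) {
    A <- if (is(dataset, "InteractionDataset")) dataset@adjacency
         else as.matrix(dataset)
    trainA <- A
    if (plan$scheme == "pairwise") {
        test <- plan$cells[plan$fold == fold, , drop = FALSE]
        trainA[test] <- 0
        testCells <- test
    } else {
        held <- which(plan$fold == fold)
        if (plan$axis == "lncrna") {
            trainA[held, ] <- 0
            testCells <- as.matrix(expand.grid(row = held,
                                               col = seq_len(ncol(A))))
        } else {
            trainA[, held] <- 0
            testCells <- as.matrix(expand.grid(row = seq_len(nrow(A)),
                                               col = held))
        }
        testCells <- unname(testCells)
    }
    list(trainA = trainA, testCells = testCells)
}

#' Run a full cross-validated evaluation of the fusion + solver pipeline
#'
#' For every fold: the test information is masked out of the adjacency
#' matrix ([maskFold()]), the two Gaussian interaction-profile kernels are
#' recomputed from the masked matrix only, they are fused with the static
#' (adjacency-independent) kernels of each axis, the regularized solver is
#' run on the masked matrix, and the scores of the fold's test cells are
#' collected. Expression, alignment and feature-based kernels are not
#' recomputed — they do not depend on the adjacency, so leakage can only
#' flow through the interaction-profile kernels, which are rebuilt per
#' fold.
#'
#' Pooled metrics (the headline numbers) are computed over a vector in
#' which every known interaction appears exactly once, scored by the fold
#' that held it out. In the pairwise scheme the negatives are the
#' never-interacting cells, scored by their per-fold average; in the
#' novel-entity schemes each cell belongs to exactly one fold, so the
#' pooled vector is simply the union. Per-fold AUROC/AUPR and their means
#' are reported alongside.
#'
#' @param dataset an [InteractionDataset].
#' @param lncKernels list of static lncRNA-axis kernels (e.g. expression
#'   and feature-based); the interaction-profile kernel is added per fold.
#' @param protKernels list of static protein-axis kernels (e.g. alignment
#'   and feature-based).
#' @param plan fold plan from [pairFolds()] or [entityFolds()].
#' @param skfL,skfP [skfParams()] for the lncRNA and protein fusions.
#' @param params a [laprlsParams()] bundle.
#' @param includeTrainNegatives in the pairwise scheme, also include the
#'   current fold's training positives as label-0 cells in that fold's
#'   evaluation pool (off by default: training cells are excluded).
#' @return an evaluation report: list with `scheme`, `pooled` (vectors
#'   `score`, `label` plus `auroc`, `aupr`, `bestF1`), `perFold`
#'   (data.frame with fold-wise AUROC/AUPR), and `foldMeanAuroc`.
#' @export
runCV <- function(dataset, lncKernels, protKernels, plan,
                  skfL, skfP, params = laprlsParams(),
                  includeTrainNegatives = FALSE) {
    A <- adjacency(dataset)
    n <- nrow(A); m <- ncol(A)
    negCells <- which(A == 0, arr.ind = TRUE)
    negScoreSum <- numeric(nrow(negCells))
    posScore <- rep(NA_real_, sum(A == 1))
    posKey <- which(A == 1)           # linear indices of known positives
    perFold <- data.frame(fold = integer(), auroc = numeric(),
                          aupr = numeric(), nPos = integer(),
                          nNeg = integer())
    pooledCells <- NULL; pooledScore <- NULL; pooledLabel <- NULL
    for (f in seq_len(plan$nFolds)) {
        msk <- maskFold(dataset, plan, f)
        gipL <- gipKernel(msk$trainA, "lncrna")
        gipP <- gipKernel(msk$trainA, "protein")
        fusedL <- fuseKernels(c(list(gipL), lncKernels), skfL)
        fusedP <- fuseKernels(c(list(gipP), protKernels), skfP)
        pred <- predictBipartite(fusedL, fusedP, msk$trainA, params)
        Fm <- pred@scores
        if (plan$scheme == "pairwise") {
            testScores <- Fm[msk$testCells]
            posScore[match(msk$testCells[, 1] +
                           (msk$testCells[, 2] - 1L) * n, posKey)] <-
                testScores
            negThisFold <- Fm[negCells]
            negScoreSum <- negScoreSum + negThisFold
            foldScores <- c(testScores, negThisFold)
            foldLabels <- c(rep(1L, length(testScores)),
                            rep(0L, nrow(negCells)))
            if (includeTrainNegatives) {
                trainCells <- plan$cells[plan$fold != f, , drop = FALSE]
                foldScores <- c(foldScores, Fm[trainCells])
                foldLabels <- c(foldLabels, rep(0L, nrow(trainCells)))
            }
        } else {
            foldScores <- Fm[msk$testCells]
            foldLabels <- A[msk$testCells]
            pooledCells <- rbind(pooledCells, msk$testCells)
            pooledScore <- c(pooledScore, foldScores)
            pooledLabel <- c(pooledLabel, foldLabels)
        }
        fa <- if (length(unique(foldLabels)) == 2L)
            c(auroc(foldScores, foldLabels),
              aupr(foldScores, foldLabels)) else c(NA_real_, NA_real_)
        perFold <- rbind(perFold, data.frame(
            fold = f, auroc = fa[1], aupr = fa[2],
            nPos = sum(foldLabels == 1L), nNeg = sum(foldLabels == 0L)))
    }
    if (plan$scheme == "pairwise") {
        pooledScore <- c(posScore, negScoreSum / plan$nFolds)
        pooledLabel <- c(rep(1L, length(posScore)),
                         rep(0L, nrow(negCells)))
    }
    best <- bestF1Threshold(pooledScore, pooledLabel)
    list(
        scheme = plan$scheme,
        pooled = list(score = pooledScore, label = pooledLabel,
                      auroc = auroc(pooledScore, pooledLabel),
                      aupr = aupr(pooledScore, pooledLabel),
                      bestF1 = best),
        perFold = perFold,
        foldMeanAuroc = mean(perFold$auroc, na.rm = TRUE)
    )
}
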