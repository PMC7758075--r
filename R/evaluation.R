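# Ranking metrics and cross-validation fold plans.

checkTwoClass <- function(labels) {
    labels <- as.integer(labels != 0)
    if (all(labels == 1L) || all(labels == 0L))
        stop("need at least one positive and one negative label")
    labels
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability
#' that a random positive outscores a random negative, with ties counted
#' one half. Exactly equivalent to brute-force pairwise comparison.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 (or logical) label vector, same length.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
auroc <- function(scores, labels) {
    labels <- checkTwoClass(labels)
    stopifnot(length(scores) == length(labels))
    P <- sum(labels == 1L)
    N <- sum(labels == 0L)
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Area under the step curve traced by sweeping the decision threshold
#' through the distinct score values from high to low: at each threshold
#' block the recall increment is multiplied by the precision attained
#' after including that block (tied scores enter together).
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(scores, labels) {
    labels <- checkTwoClass(labels)
    stopifnot(length(scores) == length(labels))
    P <- sum(labels == 1L)
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    y <- labels[o]
    last <- which(!duplicated(s, fromLast = TRUE))  # block ends
    tp <- cumsum(y)[last]
    n <- seq_along(s)[last]
    prec <- tp / n
    rec <- tp / P
    sum(diff(c(0, rec)) * prec)
}

#' Precision, recall and F1 at a threshold
#'
#' Applies the decision rule `score >= threshold` and reports
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and their
#' harmonic mean `f1 = 2 * precision * recall / (precision + recall)`.
#' When nothing is called positive, precision is reported as 0 with a
#' warning and f1 is 0.
#'
#' @inheritParams auroc
#' @param threshold decision threshold.
#' @return named list: `precision`, `recall`, `f1`, `threshold`, and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
precisionRecallF1 <- function(scores, labels, threshold) {
    labels <- as.integer(labels != 0)
    if (sum(labels) == 0L) stop("no positive labels")
    stopifnot(is.finite(threshold))
    called <- scores >= threshold
    tp <- sum(called & labels == 1L)
    fp <- sum(called & labels == 0L)
    fn <- sum(!called & labels == 1L)
    tn <- sum(!called & labels == 0L)
    if (tp + fp == 0L) {
        warning("no pairs called positive at this threshold; ",
                "precision reported as 0")
        prec <- 0
    } else prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    list(precision = prec, recall = rec, f1 = f1, threshold = threshold,
         tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Threshold maximizing the F1 score
#'
#' Scans every distinct score value as a candidate threshold and returns
#' the one with the highest F1 (ties resolved toward the lower
#' threshold, i.e. the more inclusive rule).
#'
#' @inheritParams auroc
#' @return as [precisionRecallF1()], at the argmax threshold.
#' @export
bestF1Threshold <- function(scores, labels) {
    labels <- checkTwoClass(labels)
    P <- sum(labels)
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    y <- labels[o]
    last <- which(!duplicated(s, fromLast = TRUE))
    tp <- cumsum(y)[last]
    n <- seq_along(s)[last]
    prec <- tp / n
    rec <- tp / P
    f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
    cand <- s[last]
    best <- which(f1 == max(f1))
    pick <- best[which.min(cand[best])]
    precisionRecallF1(scores, labels, cand[pick])
}

#' Top-ranked unknown interactions
#'
#' Ranks all pairs that are not known interactions in the training
#' adjacency by predicted score and returns the k best, the workflow used
#' for prospective case studies. Ties are ordered deterministically by
#' (row, column) index.
#'
#' @param prediction an [LpiPrediction] or bare score matrix.
#' @param dataset an [InteractionDataset] or 0/1 adjacency matrix
#'   (training interactions to exclude).
#' @param k number of pairs to return.
#' @return data.frame with columns `lncrna`, `protein`, `score`.
#' @export
topPredictions <- function(prediction, dataset, k = 20L) {
    Fm <- if (is(prediction, "LpiPrediction")) prediction@scores
          else as.matrix(prediction)
    A <- if (is(dataset, "InteractionDataset")) dataset@adjacency
         else as.matrix(dataset)
    stopifnot(identical(dim(Fm), dim(A)))
    unknown <- which(A == 0, arr.ind = TRUE)
    sc <- Fm[unknown]
    o <- order(-sc, unknown[, 1], unknown[, 2])[seq_len(min(k, length(sc)))]
    rn <- rownames(A); cn <- colnames(A)
    data.frame(
        lncrna = if (is.null(rn)) unknown[o, 1] else rn[unknown[o, 1]],
        protein = if (is.null(cn)) unknown[o, 2] else cn[unknown[o, 2]],
        score = sc[o],
        row.names = NULL
    )
}

#' Cross-validation fold plans
#'
#' `pairFolds()` partitions the known interaction pairs into `nFolds`
#' balanced folds (fold sizes differ by at most one) for pairwise
#' cross-validation. `entityFolds()` partitions the entities of one axis
#' instead, for the novel-lncRNA / novel-protein protocols in which a
#' held-out entity loses its entire interaction profile. Both are
#' reproducible under `seed`.
#'
#' @param dataset an [InteractionDataset].
#' @param nFolds number of folds (default 5).
#' @param seed integer seed for the random partition.
#' @return a fold plan: a list with `scheme`, `nFolds`, `seed`, and either
#'   `cells` (positive-pair index matrix) with `fold` per pair, or `axis`
#'   with `fold` per entity.
#' @export
pairFolds <- function(dataset, nFolds = 5L, seed = 1L) {
    A <- adjacency(dataset)
    cells <- which(A == 1, arr.ind = TRUE)
    P <- nrow(cells)
    if (P < nFolds)
        stop("fewer positive pairs (", P, ") than folds (", nFolds, ")")
    fold <- withSeed(seed, {
        sample(rep(seq_len(nFolds), foldSizes(P, nFolds)))
    })
    list(scheme = "pairwise", nFolds = as.integer(nFolds),
         seed = as.integer(seed),
         cells = unname(cells), fold = fold)
}

#' @rdname pairFolds
#' @param axis `"lncrna"` or `"protein"`: which axis's entities to hold
#'   out.
#' @export
entityFolds <- function(dataset, axis = c("lncrna", "protein"),
                        nFolds = 5L, seed = 1L) {
    axis <- match.arg(axis)
    n <- if (axis == "lncrna") length(lncrnaIds(dataset))
         else length(proteinIds(dataset))
    if (n < nFolds)
        stop("fewer entities (", n, ") than folds (", nFolds, ")")
    fold <- withSeed(seed, {
        sample(rep(seq_len(nFolds), foldSizes(n, nFolds)))
    })
    list(scheme = paste0("novel-", axis), nFolds = as.integer(nFolds),
         seed = as.integer(seed), axis = axis, fold = fold)
}
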