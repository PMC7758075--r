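test_that("ranking metrics agree with brute-force oracles", {
    set.seed(31)
    for (rep in 1:10) {
        n <- sample(10:50, 1)
        labels <- c(1, 0, rbinom(n - 2, 1, 0.3))  # both classes present
        scores <- round(rnorm(n), 1)              # induce ties
        expect_identical(auroc(scores, labels),
                         oracleAuroc(scores, labels))
        expect_equal(aupr(scores, labels), oracleAupr(scores, labels),
                     tolerance = 1e-9)
    }
})

test_that("metric edge conventions hold", {
    expect_equal(auroc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1)  # separated
    expect_equal(auroc(rep(2, 6), c(1, 0, 1, 0, 0, 1)), 0.5)  # all tied
    expect_error(auroc(1:3, c(1, 1, 1)), "negative")
    expect_error(aupr(1:3, c(0, 0, 0)), "positive")
})

test_that("precision/recall/F1 follow the confusion-count definitions", {
    # TP=2 FP=1 FN=2: scores >= 0.5 calls the first three
    scores <- c(0.9, 0.8, 0.7, 0.3, 0.2)
    labels <- c(1, 1, 0, 1, 1)
    r <- precisionRecallF1(scores, labels, 0.5)
    expect_equal(r$precision, 2 / 3)
    expect_equal(r$recall, 1 / 2)
    expect_equal(r$f1, 4 / 7)
    expect_equal(c(r$tp, r$fp, r$fn), c(2, 1, 2))

    expect_equal(precisionRecallF1(scores, labels, -10)$recall, 1)
    expect_warning(
        rEmpty <- precisionRecallF1(scores, labels, 10), "precision")
    expect_equal(rEmpty$precision, 0)
    expect_equal(rEmpty$f1, 0)
})

test_that("best-F1 scan matches exhaustive search and is rank-invariant", {
    set.seed(32)
    for (rep in 1:30) {
        n <- sample(8:30, 1)
        labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
        scores <- round(rnorm(n), 1)
        got <- bestF1Threshold(scores, labels)
        # exhaustive scan over distinct scores
        f1At <- function(t)
            suppressWarnings(precisionRecallF1(scores, labels, t)$f1)
        cand <- sort(unique(scores))
        best <- max(vapply(cand, f1At, numeric(1)))
        expect_equal(got$f1, best, tolerance = 1e-12)
        expect_equal(f1At(got$threshold), got$f1)
        # lower threshold preferred among ties
        ties <- cand[vapply(cand, f1At, numeric(1)) >= best - 1e-12]
        expect_equal(got$threshold, min(ties))
        # strictly increasing transform preserves the best F1
        got2 <- bestF1Threshold(exp(scores), labels)
        expect_equal(got2$f1, got$f1, tolerance = 1e-12)
    }
    sep <- bestF1Threshold(c(9, 8, 1, 0), c(1, 1, 0, 0))
    expect_equal(sep$f1, 1)
})

test_that("top-ranked predictions exclude known interactions", {
    Fm <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), 2, 3,
                 dimnames = list(c("L1", "L2"), c("P1", "P2", "P3")))
    A <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3,
                dimnames = dimnames(Fm))
    top <- topPredictions(Fm, A, k = 2)
    expect_equal(nrow(top), 2)
    expect_equal(top$lncrna[1], "L2")   # global argmax among unknowns
    expect_equal(top$score[1], 0.8)
    expect_false(any(top$lncrna == "L1" & top$protein == "P1"))
    # full ranking covers exactly the unknown cells
    all5 <- topPredictions(Fm, A, k = 99)
    expect_equal(nrow(all5), 5)
})

test_that("fold plans partition their universe with balanced sizes", {
    sim <- generateDataset(syntheticConfig(nLncrna = 20, nProtein = 7,
                                           density = 0.3, seed = 5))
    ds <- sim$dataset
    plan <- pairFolds(ds, 5, seed = 2)
    P <- sum(adjacency(ds))
    expect_equal(length(plan$fold), P)
    expect_true(max(table(plan$fold)) - min(table(plan$fold)) <= 1)
    expect_identical(plan$fold, pairFolds(ds, 5, seed = 2)$fold)

    ep <- entityFolds(ds, "protein", 5, seed = 3)
    expect_equal(sort(as.integer(table(ep$fold))), c(1, 1, 1, 2, 2))
    expect_equal(length(ep$fold), 7)

    expect_error(pairFolds(buildAdjacency(cbind("L1", "P1")), 5),
                 "fewer")
})

test_that("AUROC agrees with an established ROC implementation", {
    set.seed(77)
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.4)
    expect_equal(auroc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
})
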