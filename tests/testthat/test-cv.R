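skfL <- skfParams(0.9, 6)
skfP <- skfParams(0.8, 3)

cvFixture <- function(seed = 2) {
    sim <- generateDataset(syntheticConfig(seed = seed))
    list(sim = sim,
         lnc = lncrnaKernelSet(sim$dataset, sim$expression,
                               sim$lncSeqs)[-1],
         prot = proteinKernelSet(sim$dataset, sim$bitscores,
                                 sim$protSeqs)[-1])
}

test_that("fold masking zeroes exactly the held-out information", {
    fx <- cvFixture()
    ds <- fx$sim$dataset
    A <- adjacency(ds)

    plan <- pairFolds(ds, 5, seed = 4)
    covered <- NULL
    for (f in 1:5) {
        msk <- maskFold(ds, plan, f)
        expect_true(all(msk$trainA[msk$testCells] == 0))
        kept <- A; kept[msk$testCells] <- 0
        expect_equal(msk$trainA, kept)
        covered <- rbind(covered, msk$testCells)
    }
    # every positive appears in exactly one fold
    expect_equal(nrow(covered), sum(A))
    expect_equal(nrow(unique(as.data.frame(covered))), sum(A))

    ep <- entityFolds(ds, "lncrna", 5, seed = 4)
    for (f in 1:5) {
        msk <- maskFold(ds, ep, f)
        held <- which(ep$fold == f)
        expect_true(all(msk$trainA[held, ] == 0))
        expect_equal(msk$trainA[-held, ], A[-held, ])
    }
})

test_that("masked cells cannot influence the interaction-profile kernels", {
    fx <- cvFixture()
    ds <- fx$sim$dataset
    for (plan in list(pairFolds(ds, 5, seed = 6),
                      entityFolds(ds, "lncrna", 5, seed = 6),
                      entityFolds(ds, "protein", 5, seed = 6))) {
        msk <- maskFold(ds, plan, 1)
        # flip the original values of every test cell; the training
        # kernels must be bit-identical because masking zeroes them
        A2 <- adjacency(ds)
        A2[msk$testCells] <- 1 - A2[msk$testCells]
        ds2 <- new("InteractionDataset", lncrnaIds = lncrnaIds(ds),
                   proteinIds = proteinIds(ds), adjacency = A2)
        msk2 <- maskFold(ds2, plan, 1)
        expect_identical(msk$trainA, msk2$trainA)
        expect_identical(
            kernelValues(gipKernel(msk$trainA, "lncrna")),
            kernelValues(gipKernel(msk2$trainA, "lncrna")))
        expect_identical(
            kernelValues(gipKernel(msk$trainA, "protein")),
            kernelValues(gipKernel(msk2$trainA, "protein")))
    }
})

test_that("novel-entity folds give held-out entities all-zero profiles", {
    fx <- cvFixture()
    ds <- fx$sim$dataset
    ep <- entityFolds(ds, "lncrna", 5, seed = 9)
    msk <- maskFold(ds, ep, 2)
    held <- which(ep$fold == 2)
    g <- kernelValues(gipKernel(msk$trainA, "lncrna"))
    # a held-out lncRNA's similarity to an observed one is the Gaussian
    # of that profile's norm, with the bandwidth from the training matrix
    gamma <- gipKernel(msk$trainA, "lncrna")@scaleGamma
    v <- setdiff(seq_len(nrow(g)), held)[1]
    expect_equal(g[held[1], v],
                 exp(-gamma * sum(msk$trainA[v, ]^2)))
})

test_that("cross-validation recovers planted structure in all schemes", {
    fx <- cvFixture()
    ds <- fx$sim$dataset
    rep1 <- runCV(ds, fx$lnc, fx$prot, pairFolds(ds, 5, seed = 7),
                  skfL, skfP)
    expect_gt(rep1$pooled$auroc, 0.8)
    expect_equal(sum(rep1$pooled$label), sum(adjacency(ds)))
    # pooled vector: every positive once, every negative once
    expect_equal(length(rep1$pooled$score),
                 sum(adjacency(ds)) + sum(adjacency(ds) == 0))
    expect_false(any(is.na(rep1$pooled$score)))

    rep2 <- runCV(ds, fx$lnc, fx$prot,
                  entityFolds(ds, "lncrna", 5, seed = 7), skfL, skfP)
    expect_gt(rep2$pooled$auroc, 0.7)
    # novel-entity pooling covers every cell exactly once
    expect_equal(length(rep2$pooled$score), prod(dim(ds)))

    rep3 <- runCV(ds, fx$lnc, fx$prot,
                  entityFolds(ds, "protein", 5, seed = 7), skfL, skfP)
    expect_gt(rep3$pooled$auroc, 0.6)
    expect_equal(nrow(rep3$perFold), 5)
})

test_that("training scores rank above random when masking is disabled", {
    fx <- cvFixture(seed = 11)
    ds <- fx$sim$dataset
    lk <- c(list(gipKernel(ds, "lncrna")), fx$lnc)
    pk <- c(list(gipKernel(ds, "protein")), fx$prot)
    res <- lpiPredict(ds, lk, pk, skfL, skfP)
    Fm <- predictionScores(res$prediction)
    A <- adjacency(ds)
    expect_gt(auroc(as.vector(Fm), as.vector(A)), 0.9)
})

test_that("including training positives as negatives only adds pool cells", {
    fx <- cvFixture(seed = 12)
    ds <- fx$sim$dataset
    plan <- pairFolds(ds, 5, seed = 13)
    r0 <- runCV(ds, fx$lnc, fx$prot, plan, skfL, skfP)
    r1 <- runCV(ds, fx$lnc, fx$prot, plan, skfL, skfP,
                includeTrainNegatives = TRUE)
    expect_equal(r1$perFold$nPos, r0$perFold$nPos)
    expect_true(all(r1$perFold$nNeg > r0$perFold$nNeg))
    # pooled headline numbers are unaffected by the per-fold pool flag
    expect_equal(r1$pooled$auroc, r0$pooled$auroc)
})
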