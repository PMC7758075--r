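test_that("column normalization is exact and fails loudly on zero columns", {
    out <- columnNormalize(matrix(c(1, 3, 2, 2), 2, 2))
    expect_equal(out, matrix(c(0.25, 0.75, 0.5, 0.5), 2, 2))
    expect_equal(columnNormalize(diag(3)), diag(3))  # fixed point
    set.seed(5)
    M <- matrix(runif(25, 0.1, 1), 5, 5)
    expect_equal(unname(colSums(columnNormalize(M))), rep(1, 5))
    M[, 3] <- 0
    dimnames(M) <- list(letters[1:5], letters[1:5])
    expect_error(columnNormalize(M), "c")
})

test_that("kNN indicators exclude self, break ties by index, sum to k", {
    s <- rbind(c(1, 0.9, 0.1), c(0.2, 1, 0.8), c(0.5, 0.5, 1))
    I <- knnIndicator(s, 1)
    expect_equal(I[1, ], c(0, 1, 0))
    expect_equal(I[3, ], c(1, 0, 0))  # tie 0.5/0.5 -> lower index
    expect_equal(unname(rowSums(I)), rep(1, 3))
    expect_equal(unname(diag(I)), rep(0, 3))

    Iall <- knnIndicator(s, 2)        # saturated: k = dim - 1
    expect_true(all(Iall[row(Iall) != col(Iall)] == 1))
    expect_error(knnIndicator(s, 3), "smaller")
})

test_that("neighbor normalization is row-stochastic on the neighborhood", {
    set.seed(6)
    s <- matrix(runif(36, 0.1, 1), 6, 6); diag(s) <- 1
    I <- knnIndicator(s, 3)
    Phi <- neighborNormalize(s, I)
    expect_equal(unname(rowSums(Phi)), rep(1, 6))
    expect_true(all(Phi[I == 0] == 0))

    # uniform off-diagonal with saturated k -> uniform 1/(n-1)
    u <- matrix(0.4, 4, 4); diag(u) <- 1
    Phi2 <- neighborNormalize(u, knnIndicator(u, 3))
    expect_equal(unname(Phi2[1, -1]), rep(1 / 3, 3))

    sBad <- s; sBad[2, ] <- 0; diag(sBad) <- 1
    Ibad <- knnIndicator(sBad, 3)
    sBad2 <- sBad; sBad2[2, -2] <- 0
    expect_error(neighborNormalize(sBad2, Ibad), "neighborhood")
})

test_that("cross-diffusion matches the independent loop oracle", {
    for (seed in 1:4) {
        tri <- randomKernelTriple(4, seed)
        theta <- lapply(tri, columnNormalize)
        ind <- lapply(tri, knnIndicator, k = 2)
        phi <- Map(neighborNormalize, tri, ind)
        for (z in c(0L, 1L, 2L, 5L)) {
            got <- skfDiffuse(theta, phi, skfParams(0.7, 2, z))
            want <- oracleSkf(theta, phi, 0.7, z)
            expect_equal(got, want, tolerance = 1e-12)
            expect_true(all(got >= -1e-15))  # nonnegative closure
        }
        # z = 0 is the plain average of the inputs
        expect_equal(skfDiffuse(theta, phi, skfParams(0.7, 2, 0L)),
                     Reduce(`+`, theta) / 3)
    }
})

test_that("diffusion of z rounds composes z single-step operators", {
    tri <- randomKernelTriple(5, 99)
    theta <- lapply(tri, columnNormalize)
    ind <- lapply(tri, knnIndicator, k = 2)
    phi <- Map(neighborNormalize, tri, ind)
    # stepping the oracle one round at a time, re-feeding its state,
    # must agree with the z-round call
    oneStep <- function(state, theta0) {
        lapply(seq_along(state), function(q) {
            restL <- Reduce(`+`, state[-q])
            rest0 <- Reduce(`+`, theta0[-q])
            (0.7 / 2) * (phi[[q]] %*% restL %*% t(phi[[q]])) +
                (0.3 / 2) * rest0
        })
    }
    st <- theta
    for (i in 1:3) st <- oneStep(st, theta)
    expect_equal(skfDiffuse(theta, phi, skfParams(0.7, 2, 3L)),
                 Reduce(`+`, st) / 3, tolerance = 1e-12)
})

test_that("agreement weights realize the three-branch indicator rule", {
    I1 <- matrix(c(1, 0, 1, 0), 2, 2)
    I2 <- matrix(c(1, 0, 0, 0), 2, 2)
    I3 <- matrix(c(1, 0, 1, 0), 2, 2)
    W <- agreementWeights(list(I1, I2, I3))
    expect_equal(W[1, 1], 1)     # (1,1,1)
    expect_equal(W[2, 1], 0)     # (0,0,0)
    expect_equal(W[1, 2], 0.5)   # (1,0,1)
    expect_true(all(W %in% c(0, 0.5, 1)))
})

test_that("full fusion masks the average by neighborhood agreement", {
    tri <- randomKernelTriple(4, 17)
    # three identical kernels: indicators coincide, so w is 1 on the
    # shared kNN sets and 0 elsewhere (off-diagonal included)
    st <- fuseKernels(list(tri[[1]], tri[[1]], tri[[1]]),
                      skfParams(0.9, 2, 2L))
    I <- knnIndicator(tri[[1]], 2)
    expect_equal(agreementMatrix(st), ifelse(I == 1, 1, 0))
    expect_true(all(fusedSimilarity(st)[I == 0] == 0))

    # disagreeing non-neighbors are exactly zeroed
    st2 <- fuseKernels(tri, skfParams(0.9, 2, 2L))
    allZero <- Reduce(`+`, st2@indicators) == 0
    expect_true(all(fusedSimilarity(st2)[allZero] == 0))
    # conservation at round 0
    for (q in 1:3) {
        expect_equal(unname(colSums(st2@theta[[q]])), rep(1, 4))
        expect_equal(unname(rowSums(st2@phi[[q]])), rep(1, 4))
    }
})

test_that("fusion is equivariant under entity relabeling", {
    tri <- randomKernelTriple(6, 23)
    perm <- c(3, 1, 6, 2, 5, 4)
    S1 <- fusedSimilarity(fuseKernels(tri, skfParams(0.8, 2, 3L)))
    triP <- lapply(tri, function(M) M[perm, perm])
    S2 <- fusedSimilarity(fuseKernels(triP, skfParams(0.8, 2, 3L)))
    expect_equal(S2, S1[perm, perm], tolerance = 1e-12)
})

test_that("default benchmark-scale parameters run on a matching synthetic shape", {
    cfg <- syntheticConfig(nLncrna = 120, nProtein = 27,
                           density = 0.15, seed = 8)
    sim <- generateDataset(cfg)
    g <- gipKernel(sim$dataset, "protein")
    e <- alignmentSimilarity(sim$bitscores)
    st <- fuseKernels(list(g, e, g), skfParams(0.8, 3, 5L))
    expect_true(all(is.finite(fusedSimilarity(st))))
    # lncRNA axis at its calibrated neighbor scale relative to n
    gl <- gipKernel(sim$dataset, "lncrna")
    stL <- fuseKernels(list(gl, gl, gl), skfParams(0.9, 99, 5L))
    expect_true(all(is.finite(fusedSimilarity(stL))))
})
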