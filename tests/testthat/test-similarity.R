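test_that("interaction-profile kernel matches hand evaluation on I2", {
    g <- gipKernel(diag(2), "lncrna")
    S <- kernelValues(g)
    # gamma = 2 / (1 + 1) = 1; squared distance between e1 and e2 is 2
    expect_equal(g@scaleGamma, 1)
    expect_equal(S[1, 2], exp(-2))
    expect_equal(diag(S), c(1, 1))
    expect_true(isSymmetric(S))

    expect_error(gipKernel(matrix(0, 3, 2), "lncrna"),
                 "division by zero")
})

test_that("interaction-profile kernel has unit diagonal and symmetry", {
    set.seed(7)
    for (rep in 1:5) {
        A <- matrix(rbinom(40, 1, 0.3), 8, 5)
        if (sum(A) == 0) A[1, 1] <- 1
        for (ax in c("lncrna", "protein")) {
            S <- kernelValues(gipKernel(A, ax))
            expect_equal(max(abs(S - t(S))), 0)
            expect_equal(unname(diag(S)),
                         rep(1, if (ax == "lncrna") 8 else 5))
            expect_true(all(S >= 0 & S <= 1))
        }
    }
})

test_that("interaction-profile kernel is permutation-equivariant", {
    set.seed(12)
    A <- matrix(rbinom(48, 1, 0.4), 8, 6,
                dimnames = list(paste0("L", 1:8), paste0("P", 1:6)))
    perm <- sample(8)
    S1 <- kernelValues(gipKernel(A, "lncrna"))
    S2 <- kernelValues(gipKernel(A[perm, ], "lncrna"))
    expect_equal(S2, S1[perm, perm])
})

test_that("expression kernel maps correlations onto [0,1] with zero diagonal", {
    prof <- rbind(u = c(1, 2, 3), v = c(2, 4, 6), w = c(3, 2, 1))
    S <- kernelValues(expressionSimilarity(prof))
    expect_equal(S["u", "v"], 1)   # rho = +1
    expect_equal(S["u", "w"], 0)   # rho = -1
    expect_equal(unname(diag(S)), rep(0, 3))
    expect_true(isSymmetric(S))

    flat <- rbind(u = c(1, 2, 3), z = c(5, 5, 5))
    expect_warning(S2 <- kernelValues(expressionSimilarity(flat)),
                   "zero-variance")
    expect_equal(unname(S2["z", ]), c(0, 0))
})

test_that("alignment kernel is the row-normalized bit-score ratio", {
    b <- matrix(c(50, 18, 20, 40), 2, 2,
                dimnames = list(c("P1", "P2"), c("P1", "P2")))
    S <- kernelValues(alignmentSimilarity(b))
    expect_equal(S["P1", "P2"], 20 / 50)
    expect_equal(S["P2", "P1"], 18 / 40)
    expect_equal(unname(diag(S)), c(0, 0))
    expect_false(isSymmetric(S))

    expect_error(alignmentSimilarity(matrix(c(0, 1, 1, 5), 2)), "self")
    b2 <- matrix(c(10, 1, 12, 10), 2, 2)  # cross exceeds self
    expect_warning(S3 <- kernelValues(alignmentSimilarity(b2)),
                   "clipped")
    expect_equal(S3[1, 2], 1)
})

test_that("in-process bit scores behave like self-maximal local alignments", {
    seqs <- c(P1 = "MKVLAT", P2 = "MKVLAT", P3 = "WWCHHG")
    b <- pairwiseBitscores(seqs)
    expect_equal(b["P1", "P2"], b["P1", "P1"])   # identical sequences
    expect_true(all(diag(b) > 0))
    expect_true(b["P1", "P3"] < b["P1", "P1"])
    # deterministic
    expect_identical(b, pairwiseBitscores(seqs))
    expect_error(pairwiseBitscores(c(P1 = "")), "empty")
})

test_that("self-alignment raw score is the sum of diagonal substitution scores", {
    # ACD under BLOSUM62: A=4, C=9, D=6 -> raw 19; invert the bit formula
    b <- pairwiseBitscores(c(P1 = "ACD", P2 = "ACD"))
    raw <- (b["P1", "P1"] * log(2) + log(0.134)) / 0.3176
    expect_equal(raw, 19, tolerance = 1e-9)
})

test_that("linear neighborhood weights match the exhaustive QP oracle", {
    set.seed(21)
    for (rep in 1:6) {
        n <- 6
        X <- matrix(rnorm(n * 2), n, 2)
        k <- sample(2:4, 1)
        S <- kernelValues(lnsSimilarity(X, k = k))
        for (u in seq_len(n))
            expect_equal(S[u, ], oracleLnsRow(X, u, k),
                         tolerance = 1e-6)
        expect_equal(unname(rowSums(S)), rep(1, n), tolerance = 1e-9)
        expect_equal(unname(diag(S)), rep(0, n))
    }
})

test_that("a duplicated neighbor absorbs the full reconstruction weight", {
    X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(-4, 2), c(3, -3))
    S <- kernelValues(lnsSimilarity(X, k = 3))
    expect_equal(S[1, 2], 1, tolerance = 1e-4)
    expect_equal(sum(S[1, -2]), 0, tolerance = 1e-4)
})

test_that("symmetrized neighborhood kernel has no zero columns", {
    set.seed(33)
    X <- matrix(rnorm(60), 20, 3)
    S <- kernelValues(lnsSimilarity(X, k = 3, symmetrize = TRUE))
    expect_true(all(colSums(S) > 0))
    expect_true(isSymmetric(S))
})
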