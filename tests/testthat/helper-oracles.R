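# Independent oracles used by the unit and acceptance tests. These are
# deliberately brute-force re-derivations, sharing no code with the
# implementation paths they check.

# AUROC by exhaustive pairwise comparison (ties count one half).
oracleAuroc <- function(scores, labels) {
    sp <- scores[labels == 1]
    sn <- scores[labels == 0]
    tot <- 0
    for (p in sp) for (n in sn)
        tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(sp) * length(sn))
}

# AUPR as the area under the right-continuous precision-recall step
# curve, sweeping distinct thresholds from high to low.
oracleAupr <- function(scores, labels) {
    P <- sum(labels == 1)
    thr <- sort(unique(scores), decreasing = TRUE)
    area <- 0
    prevRec <- 0
    for (t in thr) {
        called <- scores >= t
        tp <- sum(called & labels == 1)
        prec <- tp / sum(called)
        rec <- tp / P
        area <- area + (rec - prevRec) * prec
        prevRec <- rec
    }
    area
}

# Simplex-constrained least squares by exhaustive support enumeration:
# for every nonempty support subset solve the equality-constrained
# problem on the same ridge-stabilized Gram matrix and keep the feasible
# solution with the lowest objective. Exact for strictly convex G.
oracleSimplexLS <- function(G, c0) {
    k <- nrow(G)
    best <- NULL
    bestObj <- Inf
    for (mask in 1:(2^k - 1)) {
        f <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
        kk <- length(f)
        M <- rbind(cbind(2 * G[f, f, drop = FALSE], rep(1, kk)),
                   c(rep(1, kk), 0))
        sol <- tryCatch(solve(M, c(2 * c0[f], 1)),
                        error = function(e) NULL)
        if (is.null(sol)) next
        w <- numeric(k)
        w[f] <- sol[seq_len(kk)]
        if (any(w < -1e-9)) next
        obj <- drop(t(w) %*% G %*% w - 2 * sum(c0 * w))
        if (obj < bestObj - 1e-12) {
            bestObj <- obj
            best <- pmax(w, 0)
        }
    }
    best
}

# LNS weights for one entity by the exhaustive oracle, mirroring the
# neighbor selection and ridge convention of the implementation.
oracleLnsRow <- function(X, u, k, ridge = 1e-6) {
    n <- nrow(X)
    d2 <- as.matrix(dist(X))^2
    others <- setdiff(seq_len(n), u)
    nb <- others[order(d2[u, others], others)][seq_len(k)]
    Xn <- X[nb, , drop = FALSE]
    G <- Xn %*% t(Xn)
    tr <- sum(diag(G))
    G <- G + (if (tr > 0) ridge * tr else ridge) * diag(k)
    w <- oracleSimplexLS(G, as.vector(Xn %*% X[u, ]))
    out <- numeric(n)
    out[nb] <- w
    out
}

# One cross-diffusion pass written directly from the update rule, entry
# by entry in matrix form, with no shared code.
oracleSkf <- function(theta0, phi, alpha, z) {
    K <- length(theta0)
    cur <- theta0
    if (z > 0) for (round in seq_len(z)) {
        nxt <- vector("list", K)
        for (q in seq_len(K)) {
            restL <- 0
            rest0 <- 0
            for (r in seq_len(K)) if (r != q) {
                restL <- restL + cur[[r]]
                rest0 <- rest0 + theta0[[r]]
            }
            nxt[[q]] <- (alpha / (K - 1)) *
                (phi[[q]] %*% restL %*% t(phi[[q]])) +
                ((1 - alpha) / (K - 1)) * rest0
        }
        cur <- nxt
    }
    out <- 0
    for (q in seq_len(K)) out <- out + cur[[q]]
    out / K
}

# Random kernel triple over n entities: symmetric nonnegative with unit
# diagonal, safe for normalization.
randomKernelTriple <- function(n, seed) {
    set.seed(seed)
    lapply(1:3, function(q) {
        M <- matrix(runif(n * n, 0.05, 1), n, n)
        M <- (M + t(M)) / 2
        diag(M) <- 1
        M
    })
}

# Tiny deterministic dataset for data-io and kernel tests.
tinyDataset <- function() {
    pairs <- rbind(c("L1", "P1"), c("L1", "P2"), c("L2", "P2"),
                   c("L3", "P3"))
    buildAdjacency(pairs, c("L1", "L2", "L3"), c("P1", "P2", "P3"))
}
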