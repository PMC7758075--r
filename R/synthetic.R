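# Fully synthetic bipartite interaction data with planted low-rank
# structure, so the whole pipeline is testable without any external
# download. The planted cluster signal is carried by every feature
# channel (interactions, expression, sequence composition, bit scores),
# mirroring how each individual similarity source of real data is
# informative on its own.

#' Configuration for the synthetic-data generator
#'
#' @param nLncrna,nProtein numbers of lncRNAs and proteins.
#' @param latentRank number of planted latent factors (clusters).
#' @param density target fraction of positive cells in the adjacency.
#' @param noise probability of flipping each adjacency cell after
#'   thresholding (label noise), in \[0, 0.5).
#' @param seqLenLnc,seqLenProt length ranges (min, max) for the generated
#'   RNA and protein sequences.
#' @param expressionDim number of expression conditions (tissues).
#' @param seed integer seed; the whole artifact set is a deterministic
#'   function of the configuration.
#' @return a validated configuration list.
#' @examples
#' cfg <- syntheticConfig(nLncrna = 20, nProtein = 8, seed = 1)
#' @export
syntheticConfig <- function(nLncrna = 60L, nProtein = 12L,
                            latentRank = 3L, density = 0.15,
                            noise = 0.02,
                            seqLenLnc = c(200L, 400L),
                            seqLenProt = c(80L, 150L),
                            expressionDim = 24L, seed = 1L) {
    stopifnot(nLncrna >= 2L, nProtein >= 2L, latentRank >= 1L,
              density > 0, density < 1, noise >= 0, noise < 0.5,
              expressionDim >= 2L,
              length(seqLenLnc) == 2L, length(seqLenProt) == 2L)
    if (ceiling(density * nLncrna * nProtein) < 1)
        stop("infeasible density: no positive cells")
    list(nLncrna = as.integer(nLncrna), nProtein = as.integer(nProtein),
         latentRank = as.integer(latentRank), density = density,
         noise = noise, seqLenLnc = as.integer(seqLenLnc),
         seqLenProt = as.integer(seqLenProt),
         expressionDim = as.integer(expressionDim),
         seed = as.integer(seed))
}

sampleSeq <- function(len, letters, probs) {
    paste(sample(letters, len, replace = TRUE, prob = probs),
          collapse = "")
}

#' Generate a synthetic interaction dataset with planted structure
#'
#' Draws latent factor matrices U (lncRNA x r) and V (protein x r) around
#' balanced cluster centroids, thresholds the factor product at the target
#' density to produce the adjacency matrix, then flips each cell with the
#' configured noise probability. The side channels inherit the same
#' latent structure: expression profiles are a linear map of U plus
#' Gaussian noise (so expression correlation tracks interaction
#' behavior), sequences are drawn from per-cluster residue compositions
#' (so composition and CTD features separate the clusters), and bit
#' scores follow a within-cluster-high / between-cluster-low template
#' with a maximal diagonal.
#'
#' @param cfg a [syntheticConfig()].
#' @return list with elements `dataset` ([InteractionDataset]),
#'   `expression` (lncRNA x tissue matrix), `lncSeqs` (`RNAStringSet`),
#'   `protSeqs` (`AAStringSet`), `bitscores` (protein x protein matrix),
#'   `clusters` (planted cluster labels per axis), and `config`.
#' @export
generateDataset <- function(cfg) {
    withSeed(cfg$seed, {
        n <- cfg$nLncrna; m <- cfg$nProtein; r <- cfg$latentRank
        lncIds <- sprintf("LNC%03d", seq_len(n))
        protIds <- sprintf("PROT%02d", seq_len(m))
        lncCluster <- rep_len(seq_len(r), n)
        protCluster <- rep_len(seq_len(r), m)
        U <- 0.25 * matrix(stats::rnorm(n * r), n, r)
        U[cbind(seq_len(n), lncCluster)] <-
            U[cbind(seq_len(n), lncCluster)] + 1
        V <- 0.25 * matrix(stats::rnorm(m * r), m, r)
        V[cbind(seq_len(m), protCluster)] <-
            V[cbind(seq_len(m), protCluster)] + 1
        M <- U %*% t(V)
        thr <- stats::quantile(M, 1 - cfg$density, names = FALSE)
        A <- (M > thr) * 1
        flip <- matrix(stats::runif(n * m) < cfg$noise, n, m)
        A[flip] <- 1 - A[flip]
        dimnames(A) <- list(lncIds, protIds)

        # expression: cluster signatures mapped through U, plus noise
        W <- matrix(stats::rnorm(r * cfg$expressionDim), r)
        E <- U %*% W +
            0.3 * matrix(stats::rnorm(n * cfg$expressionDim), n)
        dimnames(E) <- list(lncIds,
                            paste0("tissue", seq_len(cfg$expressionDim)))

        # per-cluster nucleotide compositions
        rnaComp <- matrix(0.15, r, 4)
        for (c in seq_len(r))
            rnaComp[c, 1L + (c - 1L) %% 4L] <- 0.55
        rnaComp <- rnaComp / rowSums(rnaComp)
        lncLen <- sample(seq(cfg$seqLenLnc[1], cfg$seqLenLnc[2]), n,
                         replace = TRUE)
        lncSeqs <- vapply(seq_len(n), function(i)
            sampleSeq(lncLen[i], c("A", "C", "G", "U"),
                      rnaComp[lncCluster[i], ]), character(1))
        names(lncSeqs) <- lncIds

        # per-cluster amino-acid compositions biased toward one
        # hydrophobicity group, so CTD features carry the cluster signal
        aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
        groups <- c("RKEDQN", "GASTPHY", "CLVIMFW")
        protLen <- sample(seq(cfg$seqLenProt[1], cfg$seqLenProt[2]), m,
                          replace = TRUE)
        protSeqs <- vapply(seq_len(m), function(j) {
            fav <- strsplit(groups[1L + (protCluster[j] - 1L) %% 3L],
                            "")[[1]]
            w <- ifelse(aa %in% fav, 3, 1)
            sampleSeq(protLen[j], aa, w / sum(w))
        }, character(1))
        names(protSeqs) <- protIds

        # bit scores: within-cluster high, between low, diagonal maximal
        B <- matrix(20 + 5 * stats::rnorm(m * m), m, m)
        same <- outer(protCluster, protCluster, "==")
        B[same] <- 80 + 5 * stats::rnorm(sum(same))
        B[B < 1] <- 1
        diag(B) <- 120
        dimnames(B) <- list(protIds, protIds)

        list(
            dataset = new("InteractionDataset", lncrnaIds = lncIds,
                          proteinIds = protIds, adjacency = A),
            expression = E,
            lncSeqs = Biostrings::RNAStringSet(lncSeqs),
            protSeqs = Biostrings::AAStringSet(protSeqs),
            bitscores = B,
            clusters = list(lncrna = lncCluster, protein = protCluster),
            config = cfg
        )
    })
}

#' Hold out a random fraction of the known interactions
#'
#' Removes `round(fraction * P)` of the P positive cells from the
#' adjacency matrix (setting them to 0) and returns both the masked
#' training dataset and the held-out cells, the harness for
#' recovery-style evaluation.
#'
#' @param dataset an [InteractionDataset].
#' @param fraction fraction of positives to hold out, in \[0, 1\].
#' @param seed integer seed.
#' @return list: `train` (masked [InteractionDataset]) and `heldOut`
#'   (index matrix of removed cells).
#' @export
maskPositives <- function(dataset, fraction, seed = 1L) {
    stopifnot(fraction >= 0, fraction <= 1)
    A <- adjacency(dataset)
    pos <- which(A == 1, arr.ind = TRUE)
    nHold <- round(fraction * nrow(pos))
    held <- withSeed(seed, {
        pos[sample(nrow(pos), nHold), , drop = FALSE]
    })
    A[held] <- 0
    list(
        train = new("InteractionDataset", lncrnaIds = lncrnaIds(dataset),
                    proteinIds = proteinIds(dataset), adjacency = A),
        heldOut = unname(held)
    )
}
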