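# Sequence-derived feature tables feeding the linear-neighborhood kernels.

RNA_BASES <- c("A", "C", "G", "U")

# Standard 3-group partitions of the 20 amino acids under four
# physicochemical properties (hydrophobicity, normalized van der Waals
# volume, polarity, polarizability), as used for CTD descriptors.
CTD_PROPERTIES <- list(
    hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
    vdwVolume      = c("GASTPDC", "NVEQIL", "MHKFRYW"),
    polarity       = c("LIFWCMVY", "PATGS", "HQRKNED"),
    polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW")
)

seqsAsCharacter <- function(seqs) {
    if (is(seqs, "XStringSet")) {
        out <- as.character(seqs)
    } else {
        out <- as.character(seqs)
        names(out) <- names(seqs)
    }
    if (is.null(names(out)) || anyDuplicated(names(out)))
        stop("sequences must carry unique names")
    out
}

#' Mono- and dinucleotide composition features for lncRNAs
#'
#' Represents each lncRNA as a 20-dimensional vector: the frequencies of
#' the four ribonucleotides followed by the frequencies of the sixteen
#' overlapping dinucleotides. Each block sums to one.
#'
#' @param seqs named RNA sequences (an `RNAStringSet` or named character
#'   vector over the ACGU alphabet; `T` is accepted and read as `U`).
#' @return numeric matrix, one row per lncRNA, 20 columns
#'   (`A,C,G,U, AA,AC,...,UU`).
#' @examples
#' lncrnaNucleotideFeatures(c(L1 = "ACGU"))
#' @export
lncrnaNucleotideFeatures <- function(seqs) {
    x <- chartr("T", "U", toupper(seqsAsCharacter(seqs)))
    if (any(grepl("[^ACGU]", x)))
        stop("RNA sequences must use the ACGU alphabet")
    if (any(nchar(x) < 2L))
        stop("sequences of length < 2 have no dinucleotides: ",
             paste(names(x)[nchar(x) < 2L], collapse = ", "))
    di <- as.vector(t(outer(RNA_BASES, RNA_BASES, paste0)))
    feat <- t(vapply(x, function(s) {
        ch <- strsplit(s, "")[[1]]
        mono <- table(factor(ch, levels = RNA_BASES))
        pairs <- paste0(ch[-length(ch)], ch[-1])
        dic <- table(factor(pairs, levels = di))
        c(as.numeric(mono) / length(ch),
          as.numeric(dic) / length(pairs))
    }, numeric(20L)))
    colnames(feat) <- c(RNA_BASES, di)
    feat
}

#' Composition/Transition/Distribution features for proteins
#'
#' Encodes each protein sequence under 3-group partitions of the amino
#' acids by physicochemical property. Per property: Composition (the three
#' group frequencies), Transition (frequencies of the three unordered
#' between-group adjacencies, normalized by the number of group-changing
#' adjacent pairs so the block sums to one whenever a transition exists),
#' and Distribution (for each group, the sequence positions of its first,
#' 25\%, 50\%, 75\% and last occurrence, divided by sequence length; zero
#' for an absent group). 21 values per property; the default four
#' properties give an 84-dimensional vector.
#'
#' @param seqs named protein sequences (an `AAStringSet` or named
#'   character vector over the 20-letter alphabet).
#' @param properties named list of 3-group partitions (character vectors of
#'   group member letters); defaults to hydrophobicity, normalized van der
#'   Waals volume, polarity and polarizability.
#' @param onUnknown `"error"` (default) or `"skip"`: how to treat residues
#'   outside the 20-letter alphabet; skipping drops them with a warning.
#' @return numeric matrix, one row per protein, `21 * length(properties)`
#'   columns.
#' @export
proteinCTDFeatures <- function(seqs, properties = CTD_PROPERTIES,
                               onUnknown = c("error", "skip")) {
    onUnknown <- match.arg(onUnknown)
    x <- toupper(seqsAsCharacter(seqs))
    alphabet <- "ACDEFGHIKLMNPQRSTVWY"
    hasBad <- grepl(paste0("[^", alphabet, "]"), x)
    if (any(hasBad)) {
        if (onUnknown == "error")
            stop("non-standard residues in: ",
                 paste(names(x)[hasBad], collapse = ", "))
        warning("dropping non-standard residues in: ",
                paste(names(x)[hasBad], collapse = ", "))
        x <- gsub(paste0("[^", alphabet, "]"), "", x)
    }
    if (any(nchar(x) < 2L))
        stop("protein sequences must have length >= 2")
    for (p in properties)
        if (length(p) != 3L ||
            !setequal(strsplit(paste(p, collapse = ""), "")[[1]],
                      strsplit(alphabet, "")[[1]]))
            stop("each property must partition the 20 amino acids ",
                 "into 3 groups")
    groupMaps <- lapply(properties, function(p) {
        map <- integer(0)
        for (g in 1:3) {
            letters <- strsplit(p[g], "")[[1]]
            map[letters] <- g
        }
        map
    })
    oneSeq <- function(s) {
        ch <- strsplit(s, "")[[1]]
        L <- length(ch)
        unlist(lapply(groupMaps, function(map) {
            g <- unname(map[ch])
            comp <- tabulate(g, 3L) / L
            adj <- cbind(g[-L], g[-1])
            changed <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
            trans <- numeric(3L)
            if (nrow(changed)) {
                key <- paste(pmin(changed[, 1], changed[, 2]),
                             pmax(changed[, 1], changed[, 2]))
                cnt <- table(factor(key, levels = c("1 2", "1 3", "2 3")))
                trans <- as.numeric(cnt) / nrow(changed)
            }
            distr <- unlist(lapply(1:3, function(grp) {
                pos <- which(g == grp)
                if (!length(pos)) return(numeric(5L))
                idx <- pmax(1L, ceiling(c(0, 0.25, 0.5, 0.75, 1) *
                                        length(pos)))
                idx[1] <- 1L
                pos[idx] / L
            }))
            c(comp, trans, distr)
        }))
    }
    feat <- t(vapply(x, oneSeq, numeric(21L * length(properties))))
    colnames(feat) <- unlist(lapply(names(properties), function(nm)
        paste(nm, c(paste0("C", 1:3), c("T12", "T13", "T23"),
                    paste0("D", rep(1:3, each = 5), ".",
                           rep(c(0, 25, 50, 75, 100), 3))), sep = ".")))
    feat
}
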