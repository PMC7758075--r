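#' Read a two-column interaction pair list
#'
#' Parses a plain-text table of known lncRNA-protein interactions, one pair
#' per line: the lncRNA identifier in the first column and the protein
#' identifier in the second. Lines starting with `#` and blank lines are
#' ignored. Duplicate pairs are dropped (their count is reported in the
#' `"duplicates"` attribute and via a message).
#'
#' @param path path to the pair file.
#' @param delimiter field separator; any run of whitespace by default.
#' @return a two-column character matrix of unique pairs, in first-appearance
#'   order, with attribute `duplicates` (the number of dropped repeats).
#' @examples
#' f <- tempfile()
#' writeLines(c("L1\tP1", "L2\tP1"), f)
#' readInteractionPairs(f)
#' @export
readInteractionPairs <- function(path, delimiter = "") {
    if (!file.exists(path)) stop("pair file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) stop("empty interaction pair file: ", path)
    split <- if (nzchar(delimiter)) strsplit(lines, delimiter, fixed = TRUE)
             else strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(split, length, 1L) < 2L)
    if (length(bad))
        stop("malformed pair line ", lineNo[bad[1]],
             " (need >= 2 columns): '", lines[bad[1]], "'")
    pairs <- t(vapply(split, function(x) trimws(x[1:2]), character(2)))
    colnames(pairs) <- c("lncrna", "protein")
    key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
    dup <- duplicated(key)
    if (any(dup))
        message(sum(dup), " duplicate pair(s) dropped")
    out <- pairs[!dup, , drop = FALSE]
    attr(out, "duplicates") <- sum(dup)
    out
}

#' Assemble the binary adjacency matrix of a bipartite network
#'
#' Builds an [InteractionDataset] from a pair list: `A[i, j] = 1` exactly
#' when `(lncrnaIds[i], proteinIds[j])` appears among the pairs. When the
#' identifier lists are omitted they are taken from the pair list in
#' first-appearance order, which then becomes the frozen index order of
#' every matrix derived from the dataset.
#'
#' @param pairs two-column character matrix (or data.frame) of
#'   (lncRNA, protein) pairs, as from [readInteractionPairs()].
#' @param lncrnaIds,proteinIds optional identifier orders; every id in
#'   `pairs` must appear in them.
#' @return an [InteractionDataset].
#' @examples
#' ds <- buildAdjacency(cbind("L1", "P2"), c("L1", "L2"), c("P1", "P2"))
#' adjacency(ds)
#' @export
buildAdjacency <- function(pairs, lncrnaIds = NULL, proteinIds = NULL) {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) < 2L) stop("pairs must have two columns")
    pl <- as.character(pairs[, 1])
    pp <- as.character(pairs[, 2])
    if (is.null(lncrnaIds)) lncrnaIds <- unique(pl)
    if (is.null(proteinIds)) proteinIds <- unique(pp)
    unknownL <- setdiff(pl, lncrnaIds)
    unknownP <- setdiff(pp, proteinIds)
    if (length(unknownL) || length(unknownP))
        stop("unknown identifiers in pair list: ",
             paste(c(unknownL, unknownP), collapse = ", "))
    A <- matrix(0, length(lncrnaIds), length(proteinIds),
                dimnames = list(lncrnaIds, proteinIds))
    A[cbind(match(pl, lncrnaIds), match(pp, proteinIds))] <- 1
    new("InteractionDataset", lncrnaIds = lncrnaIds,
        proteinIds = proteinIds, adjacency = A)
}

#' Read a FASTA file into a sequence set
#'
#' Thin wrapper around the Biostrings FASTA reader that applies this
#' package's conventions: the record identifier is the header token before
#' the first whitespace, sequences are upper-cased, multi-line records are
#' concatenated, and for RNA input any `T` is rewritten to `U` (lncRNA
#' sequence databases commonly store cDNA-style sequences).
#'
#' @param path FASTA file path.
#' @param alphabet `"rna"` for lncRNA sequences (returns an
#'   `RNAStringSet`), `"protein"` for amino-acid sequences (returns an
#'   `AAStringSet`).
#' @return a named `Biostrings::XStringSet`.
#' @export
readFastaSet <- function(path, alphabet = c("rna", "protein")) {
    alphabet <- match.arg(alphabet)
    raw <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids))
        stop("duplicate FASTA identifiers: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(as.character(raw))
    empty <- which(nchar(seqs) == 0L)
    if (length(empty))
        stop("FASTA record without sequence: ", ids[empty[1]])
    names(seqs) <- ids
    if (alphabet == "rna") {
        seqs <- chartr("T", "U", seqs)
        bad <- grepl("[^ACGU]", seqs)
        if (any(bad))
            stop("non-ACGU characters in RNA sequence(s): ",
                 paste(ids[bad], collapse = ", "))
        Biostrings::RNAStringSet(seqs)
    } else {
        bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
        if (any(bad))
            stop("non-standard residues in protein sequence(s): ",
                 paste(ids[bad], collapse = ", "))
        Biostrings::AAStringSet(seqs)
    }
}

#' Read an expression profile table
#'
#' Reads a TSV matrix of expression values with lncRNA identifiers in the
#' first column and one column per tissue (header row of tissue names).
#' Every profile must have the same dimension; non-numeric cells are
#' rejected with their row number, or — with `allowMissing = TRUE` —
#' imputed as an all-zero profile whose id is recorded in the
#' `"zeroImputed"` attribute so the expression kernel can assign it zero
#' similarity.
#'
#' @param path TSV path.
#' @param allowMissing impute all-zero profiles for rows with missing
#'   values instead of failing.
#' @return numeric matrix, lncRNA x tissue, with a `zeroImputed` attribute.
#' @export
readExpressionTable <- function(path, allowMissing = FALSE) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            na.strings = c("NA", "na", ""))
    if (ncol(df) < 2L) stop("expression table needs id + >=1 tissue column")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate lncRNA ids in expression table")
    vals <- df[, -1, drop = FALSE]
    suppressWarnings(storage <- vapply(vals, as.numeric, numeric(nrow(df))))
    if (nrow(df) == 1L) storage <- matrix(storage, nrow = 1L)
    badRow <- which(apply(is.na(storage), 1, any))
    imputed <- character(0)
    if (length(badRow)) {
        if (!allowMissing)
            stop("non-numeric or missing expression value(s) in row(s): ",
                 paste(badRow, collapse = ", "))
        storage[badRow, ] <- 0
        imputed <- ids[badRow]
        warning("imputed all-zero expression profiles for: ",
                paste(imputed, collapse = ", "))
    }
    rownames(storage) <- ids
    colnames(storage) <- colnames(vals)
    attr(storage, "zeroImputed") <- imputed
    storage
}

#' Read a BLAST tabular bit-score table
#'
#' Consumes the 12-column BLAST tabular format (`-outfmt 6`: query id,
#' subject id, ..., bit score last) and assembles a protein x protein
#' bit-score matrix. When several local alignments (HSPs) are reported for
#' one pair the best (maximum) bit score is kept; pairs with no reported
#' alignment score 0.
#'
#' @param path path to the tabular file.
#' @param proteinIds optional identifier order for the matrix; defaults to
#'   first-appearance order over both id columns.
#' @return square numeric bit-score matrix.
#' @export
readBitscoreTable <- function(path, proteinIds = NULL) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines)) stop("empty bit-score table: ", path)
    split <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(split, length, 1L) < 12L)
    if (length(bad))
        stop("line ", bad[1], " has fewer than 12 tab-separated columns")
    q <- vapply(split, `[`, "", 1L)
    s <- vapply(split, `[`, "", 2L)
    b <- as.numeric(vapply(split, `[`, "", 12L))
    if (any(is.na(b))) stop("non-numeric bit score encountered")
    if (is.null(proteinIds)) proteinIds <- unique(c(q, s))
    unknown <- setdiff(c(q, s), proteinIds)
    if (length(unknown))
        stop("ids absent from proteinIds: ", paste(unknown, collapse = ", "))
    B <- matrix(0, length(proteinIds), length(proteinIds),
                dimnames = list(proteinIds, proteinIds))
    for (i in seq_along(q))
        B[q[i], s[i]] <- max(B[q[i], s[i]], b[i])
    B
}
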