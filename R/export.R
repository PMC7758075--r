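# Writers for the standard input artifacts, used by the command-line
# `simulate` subcommand so that generated data round-trips through the
# same readers real data would use.

#' Write the standard input artifacts of a (synthetic) dataset
#'
#' `writePairsTSV` emits the known interactions as a two-column TSV;
#' `writeExpressionTable` the lncRNA x tissue matrix with an id column
#' and tissue header; `writeBitscoreTable` a 12-column BLAST-style
#' tabular file (query, subject, ten placeholder columns, bit score) with
#' one line per ordered pair.
#'
#' @param dataset an [InteractionDataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePairsTSV <- function(dataset, path) {
    A <- adjacency(dataset)
    cells <- which(A == 1, arr.ind = TRUE)
    writeLines(paste(rownames(A)[cells[, 1]],
                     colnames(A)[cells[, 2]], sep = "\t"), path)
    invisible(path)
}

#' @rdname writePairsTSV
#' @param expression lncRNA x tissue matrix with dimnames.
#' @export
writeExpressionTable <- function(expression, path) {
    header <- paste(c("id", colnames(expression)), collapse = "\t")
    body <- vapply(seq_len(nrow(expression)), function(i)
        paste(c(rownames(expression)[i],
                formatC(expression[i, ], format = "g", digits = 17)),
              collapse = "\t"), character(1))
    writeLines(c(header, body), path)
    invisible(path)
}

#' @rdname writePairsTSV
#' @param bitscores square bit-score matrix with dimnames.
#' @export
writeBitscoreTable <- function(bitscores, path) {
    ids <- rownames(bitscores)
    lines <- character(0)
    for (u in seq_along(ids)) for (v in seq_along(ids))
        lines <- c(lines, paste(c(ids[u], ids[v], rep("0", 9),
                                  formatC(bitscores[u, v], format = "g",
                                          digits = 17)),
                                collapse = "\t"))
    writeLines(lines, path)
    invisible(path)
}
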