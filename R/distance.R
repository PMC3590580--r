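#' Taxon-taxon distances from binary profiles
#'
#' `jaccardDistance()` computes, for every taxon pair (i, j),
#' \deqn{d_{ij} = (q + r) / (p + q + r)}
#' where `p` is the number of clusters present in both taxa, `q` the number
#' present only in i, and `r` the number present only in j. Shared
#' absences do not contribute. A pair of all-zero profiles (p + q + r = 0)
#' is assigned distance 0, with a warning, rather than NaN.
#'
#' `euclideanDistance()` computes the conventional Euclidean distance
#' between profile rows; on binary data this equals `sqrt(q + r)`, the
#' square root of the Hamming distance, and is not normalized by profile
#' length.
#'
#' @param m a [ProfileMatrix-class] with >= 2 rows.
#' @return A [stats::dist] object labelled by taxon id.
#' @seealso [neighborJoin()], [writeDistanceMatrix()]
#' @examples
#' pm <- methods::new("ProfileMatrix",
#'     bits = matrix(c(1L,1L,0L,1L, 1L,0L,1L,1L), 2, 4, byrow = TRUE,
#'                   dimnames = list(c("A","B"), paste0("C", 1:4))))
#' jaccardDistance(pm)    # (1+1)/(2+1+1) = 0.5
#' euclideanDistance(pm)  # sqrt(2)
#' @export
jaccardDistance <- function(m) {
    bits <- profileBits(m)
    if (nrow(bits) < 2L) stop("need at least 2 taxa")
    storage.mode(bits) <- "double"
    p <- tcrossprod(bits)
    rs <- rowSums(bits)
    qq <- outer(rs, rep(1, length(rs))) - p   # i-only ones
    rr <- t(qq)                               # j-only ones
    denom <- p + qq + rr
    d <- (qq + rr) / denom
    if (any(denom == 0 & upper.tri(denom))) {
        warning("taxon pair(s) with empty profiles; Jaccard distance set to 0")
        d[denom == 0] <- 0
    }
    diag(d) <- 0
    stats::as.dist(d)
}

#' @rdname jaccardDistance
#' @export
euclideanDistance <- function(m) {
    bits <- profileBits(m)
    if (nrow(bits) < 2L) stop("need at least 2 taxa")
    stats::dist(bits, method = "euclidean")
}

#' Export a distance matrix
#'
#' Writes a `dist` object as a PHYLIP square matrix (taxon count on the
#' first line, then one labelled row per taxon) or as TSV with a header.
#'
#' @param d a [stats::dist] with labels.
#' @param path output path.
#' @param format `"phylip"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
writeDistanceMatrix <- function(d, path, format = c("phylip", "tsv")) {
    format <- match.arg(format)
    m <- as.matrix(d)
    if (format == "phylip") {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(sprintf("%5d", nrow(m)), con)
        for (i in seq_len(nrow(m)))
            writeLines(paste(c(rownames(m)[i],
                               format(m[i, ], digits = 10, trim = TRUE)),
                             collapse = "  "), con)
    } else {
        df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
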