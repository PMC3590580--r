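#' Remove duplicate proteins within a proteome
#'
#' Scores every within-proteome pair with the [similarityScore()] formula
#' and treats pairs scoring at or above `threshold` (default 0.45) as
#' duplicates. Duplicate groups are the connected components of the
#' >=threshold graph, so the result does not depend on comparison order;
#' from each group the longest member is retained (ties broken by input
#' order). Only within-taxon pairs are ever compared.
#'
#' A pair at score >= 0.45 is near-identical over most of both lengths and
#' therefore necessarily shares an exact word of the prefilter size, so the
#' k-mer prefilter is applied before alignment without loss.
#'
#' @param p a [Proteome-class].
#' @param threshold duplicate cutoff in (0, 0.5], default 0.45.
#' @param params a [scoringConfig()].
#' @return A [Proteome-class] with duplicates removed, retaining the input
#'   record order.
#' @examples
#' p <- Proteome("t", c(a = strrep("MKVLTAGH", 12),
#'                      b = strrep("MKVLTAGH", 12),
#'                      c = strrep("WNDERFQL", 12)))
#' length(dedupeProteome(p))  # 2: one of a/b plus c
#' @export
dedupeProteome <- function(p, threshold = 0.45, params = scoringConfig()) {
    stopifnot(methods::is(p, "Proteome"),
              threshold > 0, threshold <= 0.5)
    seqs <- as.character(proteinSequences(p))
    n <- length(seqs)
    if (n < 2L) return(p)
    pairs <- .pairsSharingKmer(seqs, params$k)
    if (nrow(pairs) == 0L) return(p)
    aln <- .alignPairs(seqs, pairs, params)
    lens <- nchar(seqs)
    sc <- .simScore(aln$matchLength, aln$identity, lens[aln$i], lens[aln$j])
    dup <- sc >= threshold
    if (!any(dup)) return(p)
    g <- igraph::graph_from_edgelist(
        cbind(aln$i[dup], aln$j[dup]), directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    keep <- rep(TRUE, n)
    for (grp in split(seq_len(n), comp)) {
        if (length(grp) < 2L) next
        rep_idx <- grp[order(-lens[grp], grp)][1L]
        keep[setdiff(grp, rep_idx)] <- FALSE
    }
    removed <- names(seqs)[!keep]
    message("dedupeProteome: removed ", length(removed),
            " duplicate(s) from '", taxonId(p), "'")
    Proteome(taxonId(p), proteinSequences(p)[keep])
}
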