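#' Cluster homologous proteins across taxa
#'
#' Builds homolog families over the pooled proteins of all (deduplicated)
#' proteomes. Candidate pairs sharing an exact k-mer (see
#' [candidatePairs()]) are aligned with Smith-Waterman; a pair is linked
#' when the optimal local alignment (i) has fractional identity >=
#' `minIdentity` over its aligned columns, (ii) spans at least `minAlnLen`
#' columns, and (iii) covers at least `minCoverage` of the shorter
#' sequence. Clusters are the connected components of this homology graph
#' with >= 2 members; singletons are discarded. Cluster ids are assigned
#' 1..m in order of each component's lexicographically smallest
#' `taxon|protein` key, so the numbering is independent of input order.
#'
#' The coverage condition keeps short high-identity local alignments
#' between unrelated proteins (which arise by chance at 40% identity over a
#' few dozen columns) from linking families; genuine homologs at the
#' divergences this threshold targets align over most of their length.
#'
#' @param proteomes list of [Proteome-class] objects (>= 2), already
#'   deduplicated.
#' @param params a [scoringConfig()].
#' @param minIdentity minimum fractional identity over aligned columns for
#'   a homology edge (default 0.40).
#' @param minAlnLen minimum aligned columns for an edge (default 20).
#' @param minCoverage minimum fraction of the shorter sequence the
#'   alignment must span (default 0.60).
#' @return A [ClusterSet-class]; empty (with a warning) when no two
#'   proteins are homologous.
#' @seealso [buildProfileMatrix()], [dedupeProteome()]
#' @export
buildClusters <- function(proteomes, params = scoringConfig(),
                          minIdentity = 0.40, minAlnLen = 20L,
                          minCoverage = 0.60) {
    stopifnot(is.list(proteomes), length(proteomes) >= 2L,
              all(vapply(proteomes, methods::is, TRUE, "Proteome")),
              minIdentity > 0, minIdentity <= 1,
              minAlnLen >= 1L, minCoverage >= 0, minCoverage <= 1)
    taxa <- vapply(proteomes, taxonId, "")
    if (anyDuplicated(taxa))
        stop("duplicate taxon ids among proteomes: ",
             paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
    seqs <- unlist(unname(lapply(proteomes, function(p) {
        s <- as.character(proteinSequences(p))
        names(s) <- paste(taxonId(p), names(s), sep = "|")
        s
    })))
    n <- length(seqs)
    keys <- names(seqs)
    pairs <- .pairsSharingKmer(seqs, params$k)
    edges <- NULL
    if (nrow(pairs)) {
        aln <- .alignPairs(seqs, pairs, params)
        lens <- nchar(seqs)
        ok <- aln$rawScore > 0 &
            aln$identity >= minIdentity &
            aln$matchLength >= minAlnLen &
            aln$matchLength >= minCoverage * pmin(lens[aln$i], lens[aln$j])
        if (any(ok)) edges <- cbind(aln$i[ok], aln$j[ok])
    }
    if (is.null(edges)) {
        warning("no homologous pairs found; returning an empty ClusterSet")
        return(methods::new("ClusterSet",
            membership = data.frame(cluster = integer(), taxon = character(),
                                    protein = character(),
                                    stringsAsFactors = FALSE),
            sequences = Biostrings::AAStringSet()))
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    groups <- split(seq_len(n), comp)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) == 0L) {
        warning("no clusters with >= 2 members; returning an empty ClusterSet")
        return(methods::new("ClusterSet",
            membership = data.frame(cluster = integer(), taxon = character(),
                                    protein = character(),
                                    stringsAsFactors = FALSE),
            sequences = Biostrings::AAStringSet()))
    }
    minKey <- vapply(groups, function(g) min(keys[g]), "")
    groups <- groups[order(minKey)]
    memberIdx <- unlist(lapply(groups, function(g) g[order(keys[g])]),
                        use.names = FALSE)
    clusterId <- rep.int(seq_along(groups), lengths(groups))
    memberKeys <- keys[memberIdx]
    taxon <- sub("\\|.*$", "", memberKeys)
    protein <- sub("^[^|]*\\|", "", memberKeys)
    membership <- data.frame(cluster = clusterId, taxon = taxon,
                             protein = protein, stringsAsFactors = FALSE)
    methods::new("ClusterSet", membership = membership,
                 sequences = Biostrings::AAStringSet(seqs[memberIdx]))
}

#' Write the cluster membership table
#'
#' @param clusters a [ClusterSet-class].
#' @param path output TSV path; columns cluster_id, taxon_id, protein_id.
#' @return The path, invisibly.
#' @export
writeClusterTable <- function(clusters, path) {
    m <- clusterMembership(clusters)
    utils::write.table(
        data.frame(cluster_id = m$cluster, taxon_id = m$taxon,
                   protein_id = m$protein),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
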