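#' Build the binary taxa x clusters profile matrix
#'
#' Entry (i, j) is 1 iff any protein of taxon i belongs to cluster j —
#' presence, not count: a taxon contributing two paralogs to one cluster
#' still yields a single 1. Row order follows the order of `proteomes`;
#' columns are `"C1".."Cm"` in cluster-id order. A taxon none of whose
#' proteins were clustered gets an all-zero row and a warning (it carries
#' no signal for the distance stage but is kept).
#'
#' @param clusters a [ClusterSet-class] built from these proteomes.
#' @param proteomes the list of [Proteome-class] objects defining the rows.
#' @return A [ProfileMatrix-class].
#' @seealso [jaccardDistance()], [euclideanDistance()]
#' @export
buildProfileMatrix <- function(clusters, proteomes) {
    stopifnot(methods::is(clusters, "ClusterSet"), is.list(proteomes),
              all(vapply(proteomes, methods::is, TRUE, "Proteome")))
    taxa <- unname(vapply(proteomes, taxonId, ""))
    if (anyDuplicated(taxa))
        stop("duplicate taxon ids among proteomes")
    m <- nClusters(clusters)
    bits <- matrix(0L, nrow = length(taxa), ncol = m,
                   dimnames = list(taxa,
                                   if (m) paste0("C", seq_len(m)) else NULL))
    mem <- clusterMembership(clusters)
    if (nrow(mem)) {
        known <- mem$taxon %in% taxa
        if (!all(known))
            stop("cluster members reference taxa absent from 'proteomes': ",
                 paste(unique(mem$taxon[!known]), collapse = ", "))
        bits[cbind(match(mem$taxon, taxa), mem$cluster)] <- 1L
    }
    empty <- rowSums(bits) == 0L
    if (any(empty))
        warning("all-zero profile for ", sum(empty), " taxon/taxa: ",
                paste(taxa[empty], collapse = ", "))
    methods::new("ProfileMatrix", bits = bits)
}

#' Write the profile matrix as TSV
#'
#' @param matrix a [ProfileMatrix-class].
#' @param path output path; header row of cluster ids, one row per taxon
#'   with the taxon id in the first column.
#' @return The path, invisibly.
#' @export
writeProfileMatrix <- function(matrix, path) {
    bits <- profileBits(matrix)
    df <- data.frame(taxon_id = rownames(bits), bits, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
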