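#' @import methods
#' @importFrom Biostrings AAString AAStringSet readBStringSet
#'   writeXStringSet pairwiseAlignment nmatch nchar score width
#' @importFrom ape nj write.tree read.tree
#' @importFrom igraph graph_from_edgelist add_vertices components vcount
#' @importFrom jsonlite write_json fromJSON
#' @importFrom withr with_seed
#' @importFrom stats cor dist as.dist cophenetic runif var setNames
#' @importFrom utils write.table data head packageVersion
#' @importFrom tools md5sum file_path_sans_ext
NULL

#' Proteome: the protein complement of one taxon
#'
#' A `Proteome` bundles the putative protein sequences of a single taxon
#' (for plasmid comparative genomics, one plasmid) as an
#' [Biostrings::AAStringSet] whose names are the protein identifiers,
#' together with the taxon identifier.
#'
#' Validity requires a single nonempty `taxon`, at least one sequence,
#' unique nonempty protein identifiers, every sequence of length >= 1, and
#' no `"|"` in either identifier kind (`"|"` separates taxon and protein in
#' internal member keys).
#'
#' @slot taxon single character, the taxon identifier.
#' @slot sequences [Biostrings::AAStringSet], named by protein identifier.
#'
#' @seealso [readProteome()], [dedupeProteome()]
#' @exportClass Proteome
setClass("Proteome", slots = c(taxon = "character", sequences = "AAStringSet"))

setValidity("Proteome", function(object) {
    msg <- character()
    if (length(object@taxon) != 1L || !nzchar(object@taxon))
        msg <- c(msg, "'taxon' must be a single nonempty string")
    ids <- names(object@sequences)
    if (length(object@sequences) < 1L)
        msg <- c(msg, "a Proteome must contain at least one sequence")
    if (is.null(ids) || any(!nzchar(ids)))
        msg <- c(msg, "all sequences must carry nonempty protein identifiers")
    else if (anyDuplicated(ids))
        msg <- c(msg, "duplicate protein identifiers within one proteome")
    if (length(object@sequences) && any(Biostrings::width(object@sequences) < 1L))
        msg <- c(msg, "zero-length sequences are not allowed")
    if (any(grepl("|", c(object@taxon, ids), fixed = TRUE)))
        msg <- c(msg, "identifiers must not contain '|'")
    if (length(msg)) msg else TRUE
})

#' Construct a Proteome
#'
#' @param taxon single character taxon identifier.
#' @param sequences named [Biostrings::AAStringSet] or named character
#'   vector of amino-acid sequences.
#' @return A [Proteome-class] object.
#' @examples
#' p <- Proteome("plasmidA", c(p1 = "MKVLT", p2 = "GGHARN"))
#' taxonId(p)
#' @export
Proteome <- function(taxon, sequences) {
    if (!methods::is(sequences, "AAStringSet"))
        sequences <- Biostrings::AAStringSet(sequences)
    methods::new("Proteome", taxon = as.character(taxon), sequences = sequences)
}

#' ClusterSet: homolog families across taxa
#'
#' Each cluster is a family of >= 2 proteins (possibly spanning taxa)
#' connected by pairwise local-alignment homology. Cluster identifiers are
#' contiguous `1..m`, ordered by each cluster's lexicographically smallest
#' `taxon|protein` member key so that the numbering is independent of input
#' order. Member sequences are retained because profiling a new taxon
#' against the library re-aligns against them.
#'
#' @slot membership data.frame with columns `cluster` (integer), `taxon`,
#'   `protein` (character).
#' @slot sequences [Biostrings::AAStringSet] named `taxon|protein`, one
#'   entry per member.
#' @seealso [buildClusters()], [profileNewTaxon()]
#' @exportClass ClusterSet
setClass("ClusterSet",
    slots = c(membership = "data.frame", sequences = "AAStringSet"))

setValidity("ClusterSet", function(object) {
    m <- object@membership
    msg <- character()
    if (!all(c("cluster", "taxon", "protein") %in% names(m)))
        return("membership must have columns cluster, taxon, protein")
    if (nrow(m)) {
        sizes <- table(m$cluster)
        if (any(sizes < 2L))
            msg <- c(msg, "every cluster must have >= 2 members")
        ids <- sort(unique(m$cluster))
        if (!identical(as.integer(ids), seq_along(ids)))
            msg <- c(msg, "cluster ids must be contiguous 1..m")
        keys <- paste(m$taxon, m$protein, sep = "|")
        if (anyDuplicated(keys))
            msg <- c(msg, "a protein may belong to at most one cluster")
        if (!all(keys %in% names(object@sequences)))
            msg <- c(msg, "every member must have a stored sequence")
    }
    if (length(msg)) msg else TRUE
})

#' ProfileMatrix: binary taxa x clusters incidence matrix
#'
#' Row i, column j is 1 iff taxon i contributes at least one protein to
#' cluster j (presence, not count). The matrix doubles as the correlation
#' filter library: each row is the binary profile a new taxon's profile is
#' correlated against.
#'
#' @slot bits integer matrix of 0/1 with unique taxon rownames and cluster
#'   colnames (`"C1".."Cm"`).
#' @seealso [buildProfileMatrix()], [correlateProfile()]
#' @exportClass ProfileMatrix
setClass("ProfileMatrix", slots = c(bits = "matrix"))

setValidity("ProfileMatrix", function(object) {
    b <- object@bits
    msg <- character()
    if (!is.numeric(b))
        return("bits must be a numeric 0/1 matrix")
    if (nrow(b) > 0L && (is.null(rownames(b)) || any(!nzchar(rownames(b)))))
        msg <- c(msg, "rows must be named by taxon")
    else if (anyDuplicated(rownames(b)))
        msg <- c(msg, "duplicate taxon ids among rows")
    if (length(b) && !all(b %in% c(0, 1)))
        msg <- c(msg, "entries must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' BinaryProfile: one taxon's presence/absence vector over clusters
#'
#' @slot taxon single character taxon identifier.
#' @slot bits named integer vector of 0/1, one entry per cluster, in
#'   library cluster order.
#' @seealso [profileNewTaxon()]
#' @exportClass BinaryProfile
setClass("BinaryProfile", slots = c(taxon = "character", bits = "integer"))

setValidity("BinaryProfile", function(object) {
    if (length(object@taxon) != 1L || !nzchar(object@taxon))
        return("'taxon' must be a single nonempty string")
    if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
        return("bits must be 0/1")
    TRUE
})

#' CorrelationReport: placement decision for one new taxon
#'
#' Pearson product-moment correlation of a new taxon's binary profile
#' against every library profile, the best-matching library taxon, and the
#' acceptance decision at the configured threshold. Acceptance is purely
#' the correlation criterion; corroborating biological evidence is left to
#' the analyst.
#'
#' @slot newTaxon taxon identifier of the profiled proteome.
#' @slot coefficients named numeric, one Pearson coefficient per library
#'   taxon, each in [-1, 1].
#' @slot bestMatch library taxon with the maximal coefficient.
#' @slot bestValue the maximal coefficient.
#' @slot accepted TRUE iff `bestValue >= threshold`.
#' @slot threshold the acceptance threshold used.
#' @seealso [correlateProfile()], [augmentTree()]
#' @exportClass CorrelationReport
setClass("CorrelationReport",
    slots = c(newTaxon = "character", coefficients = "numeric",
              bestMatch = "character", bestValue = "numeric",
              accepted = "logical", threshold = "numeric"))

setValidity("CorrelationReport", function(object) {
    msg <- character()
    if (length(object@coefficients) &&
        any(object@coefficients < -1 - 1e-12 | object@coefficients > 1 + 1e-12))
        msg <- c(msg, "coefficients must lie in [-1, 1]")
    if (length(object@bestValue) == 1L && length(object@threshold) == 1L &&
        !identical(object@accepted, object@bestValue >= object@threshold))
        msg <- c(msg, "accepted must equal bestValue >= threshold")
    if (length(msg)) msg else TRUE
})
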