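#' Accessors for ProfileTree classes
#'
#' Small accessor generics: `taxonId()` returns the taxon identifier of a
#' [Proteome-class] or [BinaryProfile-class]; `proteinSequences()` the
#' sequences of a [Proteome-class] or [ClusterSet-class];
#' `clusterMembership()` the membership table of a [ClusterSet-class];
#' `nClusters()` its cluster count; `profileTaxa()` the row taxa of a
#' [ProfileMatrix-class]; `profileBits()` the 0/1 data of a
#' [ProfileMatrix-class] or [BinaryProfile-class].
#'
#' @param x the object.
#' @return See the per-generic description above.
#' @name accessors
#' @examples
#' p <- Proteome("t1", c(a = "MKVLT"))
#' taxonId(p)
#' proteinSequences(p)
NULL

#' @rdname accessors
#' @export
setGeneric("taxonId", function(x) standardGeneric("taxonId"))

#' @rdname accessors
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

#' @rdname accessors
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("profileTaxa", function(x) standardGeneric("profileTaxa"))

#' @rdname accessors
#' @export
setGeneric("profileBits", function(x) standardGeneric("profileBits"))

#' @rdname accessors
#' @export
setMethod("taxonId", "Proteome", function(x) x@taxon)

#' @rdname accessors
#' @export
setMethod("taxonId", "BinaryProfile", function(x) x@taxon)

#' @rdname accessors
#' @export
setMethod("proteinSequences", "Proteome", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("proteinSequences", "ClusterSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("clusterMembership", "ClusterSet", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterSet", function(x) {
    if (nrow(x@membership)) max(x@membership$cluster) else 0L
})

#' @rdname accessors
#' @export
setMethod("profileTaxa", "ProfileMatrix", function(x) rownames(x@bits))

#' @rdname accessors
#' @export
setMethod("profileBits", "ProfileMatrix", function(x) x@bits)

#' @rdname accessors
#' @export
setMethod("profileBits", "BinaryProfile", function(x) x@bits)

#' @describeIn accessors number of sequences in a Proteome.
#' @export
setMethod("length", "Proteome", function(x) length(x@sequences))

#' Coerce a ProfileMatrix to a base matrix
#' @param x a [ProfileMatrix-class].
#' @param ... unused.
#' @return integer 0/1 matrix with taxon rownames and cluster colnames.
#' @export
setMethod("as.matrix", "ProfileMatrix", function(x, ...) x@bits)

setMethod("show", "Proteome", function(object) {
    cat("Proteome of taxon '", object@taxon, "': ",
        length(object@sequences), " proteins (widths ",
        min(Biostrings::width(object@sequences)), "-",
        max(Biostrings::width(object@sequences)), ")\n", sep = "")
})

setMethod("show", "ClusterSet", function(object) {
    m <- object@membership
    cat("ClusterSet:", nClusters(object), "clusters,", nrow(m), "member proteins")
    if (nrow(m))
        cat(" across", length(unique(m$taxon)), "taxa")
    cat("\n")
})

setMethod("show", "ProfileMatrix", function(object) {
    cat("ProfileMatrix:", nrow(object@bits), "taxa x",
        ncol(object@bits), "clusters; fill",
        if (length(object@bits)) round(mean(object@bits), 3) else NA, "\n")
})

setMethod("show", "BinaryProfile", function(object) {
    cat("BinaryProfile of '", object@taxon, "': ",
        sum(object@bits), "/", length(object@bits),
        " clusters present\n", sep = "")
})

setMethod("show", "CorrelationReport", function(object) {
    cat("CorrelationReport for '", object@newTaxon, "'\n", sep = "")
    cat("  best match: ", object@bestMatch, " (r = ",
        format(object@bestValue, digits = 4), ")\n", sep = "")
    cat("  decision:   ",
        if (object@accepted) "ACCEPTED" else "rejected",
        " at threshold ", object@threshold,
        " (correlation criterion only; corroborate with biological",
        " evidence)\n", sep = "")
})
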