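#' Profile a new taxon against the cluster library
#'
#' Computes the binary profile of a proteome that was not part of the
#' library build: bit j is 1 iff some protein of `p` attains a
#' [similarityScore()] strictly greater than `membershipThreshold`
#' (default 0.2) against at least one member sequence of cluster j. The
#' strict comparison follows the membership rule; contrast the
#' >=-comparison of the 0.45 duplicate cutoff. Alignment runs only on
#' protein/member pairs sharing an exact k-mer (the prefilter). Proteins
#' matching no cluster are ignored — insertion never creates clusters; a
#' full rebuild is the remedy when the library is too incomplete.
#'
#' @param p a [Proteome-class] for the new taxon.
#' @param clusters the library [ClusterSet-class] (with member sequences).
#' @param params a [scoringConfig()].
#' @param membershipThreshold cluster-membership score cutoff, default 0.2.
#' @return A [BinaryProfile-class] in library cluster order.
#' @seealso [correlateProfile()], [augmentTree()]
#' @export
profileNewTaxon <- function(p, clusters, params = scoringConfig(),
                            membershipThreshold = 0.2) {
    stopifnot(methods::is(p, "Proteome"), methods::is(clusters, "ClusterSet"),
              membershipThreshold >= 0, membershipThreshold < 0.5)
    if (length(p) == 0L) stop("empty proteome")
    m <- nClusters(clusters)
    bits <- integer(m)
    if (m) names(bits) <- paste0("C", seq_len(m))
    if (m == 0L)
        return(methods::new("BinaryProfile", taxon = taxonId(p), bits = bits))
    new_seqs <- as.character(proteinSequences(p))
    mem <- clusterMembership(clusters)
    lib_seqs <- as.character(proteinSequences(clusters))
    hits <- .crossPairsSharingKmer(new_seqs, lib_seqs, params$k)
    if (nrow(hits)) {
        all_seqs <- c(new_seqs, unname(lib_seqs))
        pairs <- cbind(hits[, 1L], hits[, 2L] + length(new_seqs))
        aln <- .alignPairs(all_seqs, pairs, params)
        lens <- nchar(all_seqs)
        sc <- .simScore(aln$matchLength, aln$identity,
                        lens[aln$i], lens[aln$j])
        member_cluster <- mem$cluster[aln$j - length(new_seqs)]
        hit_clusters <- unique(member_cluster[sc > membershipThreshold])
        bits[hit_clusters] <- 1L
    }
    methods::new("BinaryProfile", taxon = taxonId(p), bits = bits)
}

#' Correlate a profile against the library
#'
#' Pearson product-moment correlation of a new taxon's binary profile
#' against every row of the library [ProfileMatrix-class]. A
#' zero-variance vector (all-0 or all-1 profile or library row) has no
#' defined Pearson coefficient; such comparisons are reported as 0 with a
#' warning. The best-matching library taxon (first row in library order on
#' ties) and the acceptance decision at `threshold` (default 0.5,
#' `bestValue >= threshold`) complete the report.
#'
#' @param profile a [BinaryProfile-class] whose length equals the library
#'   column count.
#' @param library the [ProfileMatrix-class] correlation filter library.
#' @param threshold acceptance threshold on the best coefficient,
#'   default 0.5.
#' @return A [CorrelationReport-class].
#' @export
correlateProfile <- function(profile, library, threshold = 0.5) {
    stopifnot(methods::is(profile, "BinaryProfile"),
              methods::is(library, "ProfileMatrix"))
    bits <- profileBits(library)
    v <- as.numeric(profileBits(profile))
    if (length(v) != ncol(bits))
        stop("profile length (", length(v),
             ") does not match library cluster count (", ncol(bits), ")")
    rowVar <- apply(bits, 1L, stats::var)
    flat <- rowVar == 0 | stats::var(v) == 0
    co <- rep(0, nrow(bits))
    names(co) <- rownames(bits)
    if (any(!flat))
        co[!flat] <- as.numeric(stats::cor(t(bits[!flat, , drop = FALSE]), v))
    if (any(flat))
        warning("zero-variance profile comparison(s) reported as 0: ",
                paste(rownames(bits)[flat], collapse = ", "))
    best <- which.max(co)
    methods::new("CorrelationReport",
                 newTaxon = taxonId(profile), coefficients = co,
                 bestMatch = names(co)[best], bestValue = unname(co[best]),
                 accepted = unname(co[best]) >= threshold,
                 threshold = threshold)
}

#' Insert new taxa into the dendrogram via the correlation filter
#'
#' Correlates each new taxon's binary profile against the original
#' library, appends every accepted profile as a new matrix row (all
#' decisions are made against the original library, then accepted rows are
#' appended together), recomputes the chosen distance matrix on the
#' augmented matrix, and rebuilds the neighbor-joining dendrogram from
#' scratch. Rejected profiles are reported but not inserted; with zero
#' accepted profiles the tree of the original library is returned
#' unchanged.
#'
#' As a sanity check, each accepted taxon's nearest original-library leaf
#' by path length in the new tree is compared with its best-correlated
#' library taxon; a mismatch raises a warning (a newly placed taxon is
#' expected to sit near the profile it correlates with most).
#'
#' @param library the [ProfileMatrix-class] correlation filter library.
#' @param newProfiles list of [BinaryProfile-class] objects (from
#'   [profileNewTaxon()]).
#' @param metric `"jaccard"` (default) or `"euclidean"`.
#' @param threshold correlation acceptance threshold, default 0.5.
#' @return A list with elements `tree` (ape `phylo`), `reports` (list of
#'   [CorrelationReport-class]) and `accepted` (character vector of
#'   inserted taxon ids).
#' @export
augmentTree <- function(library, newProfiles,
                        metric = c("jaccard", "euclidean"),
                        threshold = 0.5) {
    metric <- match.arg(metric)
    stopifnot(methods::is(library, "ProfileMatrix"), is.list(newProfiles),
              all(vapply(newProfiles, methods::is, TRUE, "BinaryProfile")))
    bits <- profileBits(library)
    reports <- lapply(newProfiles, correlateProfile, library = library,
                      threshold = threshold)
    acc <- vapply(reports, methods::slot, TRUE, "accepted")
    newTaxa <- vapply(reports, methods::slot, "", "newTaxon")
    if (anyDuplicated(c(rownames(bits), newTaxa[acc])))
        stop("taxon id collision between library and inserted taxa")
    aug <- bits
    if (any(acc)) {
        extra <- do.call(rbind, lapply(newProfiles[acc], profileBits))
        rownames(extra) <- newTaxa[acc]
        aug <- rbind(bits, extra)
    } else {
        message("augmentTree: no profile accepted at threshold ", threshold,
                "; returning the original tree")
    }
    pm <- methods::new("ProfileMatrix", bits = aug)
    d <- switch(metric, jaccard = jaccardDistance(pm),
                euclidean = euclideanDistance(pm))
    tree <- neighborJoin(d)
    if (any(acc)) {
        paths <- stats::cophenetic(tree)
        for (rep_i in which(acc)) {
            tx <- newTaxa[rep_i]
            libDist <- paths[tx, rownames(bits)]
            nearest <- names(libDist)[which.min(libDist)]
            if (nearest != reports[[rep_i]]@bestMatch)
                warning("inserted taxon '", tx, "' is nearest to '", nearest,
                        "' in the tree but best-correlated with '",
                        reports[[rep_i]]@bestMatch, "'")
        }
    }
    list(tree = tree, reports = reports, accepted = newTaxa[acc])
}
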