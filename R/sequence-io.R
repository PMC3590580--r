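.AA_STANDARD20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                    "F","P","S","T","W","Y","V")

#' Read one proteome from a FASTA file
#'
#' Parses an amino-acid FASTA file into a [Proteome-class]. Sequences are
#' upper-cased; trailing stop characters (`*`) are stripped; any character
#' outside the 20 standard residues plus `X` (including the ambiguity
#' codes B, Z, J, U, O) is mapped to `X` with a warning. The protein
#' identifier is the first whitespace-delimited token of the FASTA header.
#'
#' @param path path to a FASTA file.
#' @param taxonId taxon identifier to attach to every record.
#' @return A [Proteome-class].
#' @section Errors:
#' An empty file, an entry with an empty sequence (before or after stop
#' stripping), an internal `*`, or duplicated identifiers raise an error
#' naming the offending entry.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 some description", "mkvlt", ">p2", "GGHARN"), f)
#' readProteome(f, "plasmidA")
#' @export
readProteome <- function(path, taxonId) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("FASTA file contains no sequences: ", path)
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    if (any(!nzchar(ids)))
        stop("FASTA entry with empty header in ", path)
    if (anyDuplicated(ids))
        stop("duplicate protein identifiers in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(as.character(raw))
    seqs <- sub("\\*+$", "", seqs)
    bad <- !nzchar(seqs)
    if (any(bad))
        stop("empty sequence for entry '", ids[which(bad)[1L]], "' in ", path)
    internalStop <- grepl("*", seqs, fixed = TRUE)
    if (any(internalStop))
        stop("internal stop character '*' in entry '",
             ids[which(internalStop)[1L]], "' in ", path)
    nonstd <- grepl(sprintf("[^%sX]", paste(.AA_STANDARD20, collapse = "")),
                    seqs)
    if (any(nonstd)) {
        warning("mapped non-standard residue letters to X in ",
                sum(nonstd), " entries of ", path,
                " (", paste(utils::head(ids[nonstd], 5L), collapse = ", "),
                if (sum(nonstd) > 5L) ", ..." else "", ")")
        seqs <- gsub(sprintf("[^%sX]", paste(.AA_STANDARD20, collapse = "")),
                     "X", seqs)
    }
    names(seqs) <- ids
    Proteome(taxonId, seqs)
}

.sanitizeLabels <- function(labels) {
    clean <- gsub("[^A-Za-z0-9_.-]", "_", labels)
    changed <- clean != labels
    if (any(changed))
        message("sanitized ", sum(changed), " tree label(s) for Newick: ",
                paste(sprintf("'%s' -> '%s'", labels[changed], clean[changed]),
                      collapse = ", "))
    clean
}

#' Write a dendrogram in Newick format
#'
#' Serializes an [ape::phylo] tree (as produced by [neighborJoin()]) to a
#' `.nwk` file with branch lengths. Labels are restricted to
#' `[A-Za-z0-9_.-]`; other characters are replaced by `_` with a logged
#' mapping, for maximal compatibility with downstream tree viewers.
#'
#' @param tree a `phylo` object with >= 2 tips.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeNewick <- function(tree, path) {
    stopifnot(inherits(tree, "phylo"))
    if (length(tree$tip.label) < 2L)
        stop("a Newick tree needs at least 2 leaves")
    tree$tip.label <- .sanitizeLabels(tree$tip.label)
    ok <- ape::write.tree(tree, file = path)
    invisible(path)
}

.LIBRARY_FORMAT <- "ProfileTree-library"
.LIBRARY_VERSION <- 1L

#' Persist and restore the correlation filter library
#'
#' `saveLibrary()` writes the [ClusterSet-class] (including every member
#' sequence, which new-taxon profiling re-aligns against) and the
#' [ProfileMatrix-class] to a single versioned JSON file; `loadLibrary()`
#' restores them losslessly. Saving the same objects twice yields
#' byte-identical files.
#'
#' @param clusters a [ClusterSet-class].
#' @param matrix a [ProfileMatrix-class] whose column count and order match
#'   `clusters`.
#' @param path file path of the library archive.
#' @return `saveLibrary()`: the path, invisibly. `loadLibrary()`: a list
#'   with elements `clusters` and `matrix`.
#' @section Errors:
#' Saving a matrix with zero taxa, or a matrix whose columns do not match
#' the cluster set, is an error. Loading a truncated or non-library file,
#' or a library written under a different format version, is an error.
#' @examples
#' \dontrun{
#' saveLibrary(clusters, pm, "library.json")
#' lib <- loadLibrary("library.json")
#' }
#' @export
saveLibrary <- function(clusters, matrix, path) {
    stopifnot(methods::is(clusters, "ClusterSet"),
              methods::is(matrix, "ProfileMatrix"))
    bits <- profileBits(matrix)
    if (nrow(bits) == 0L)
        stop("refusing to save a library with zero taxa")
    if (ncol(bits) != nClusters(clusters))
        stop("profile matrix has ", ncol(bits),
             " columns but the cluster set has ", nClusters(clusters),
             " clusters")
    m <- clusterMembership(clusters)
    payload <- list(
        format = .LIBRARY_FORMAT,
        version = .LIBRARY_VERSION,
        taxa = rownames(bits),
        cluster_ids = colnames(bits),
        membership = list(cluster = m$cluster, taxon = m$taxon,
                          protein = m$protein),
        sequences = list(key = names(proteinSequences(clusters)),
                         seq = as.character(proteinSequences(clusters))),
        profiles = list(n_taxa = nrow(bits), n_clusters = ncol(bits),
                        values = as.integer(t(bits))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
    invisible(path)
}

#' @rdname saveLibrary
#' @export
loadLibrary <- function(path) {
    if (!file.exists(path)) stop("no such library file: ", path)
    payload <- tryCatch(
        jsonlite::fromJSON(path, simplifyVector = TRUE),
        error = function(e) stop("corrupt or truncated library file '",
                                 path, "': ", conditionMessage(e)))
    if (!identical(payload$format, .LIBRARY_FORMAT))
        stop("'", path, "' is not a ", .LIBRARY_FORMAT, " archive")
    if (!identical(as.integer(payload$version), .LIBRARY_VERSION))
        stop("library format version mismatch in '", path, "': found ",
             payload$version, ", this build reads version ",
             .LIBRARY_VERSION)
    needed <- c("taxa", "cluster_ids", "membership", "sequences", "profiles")
    if (!all(needed %in% names(payload)))
        stop("corrupt or truncated library file '", path, "': missing ",
             paste(setdiff(needed, names(payload)), collapse = ", "))
    seqs <- Biostrings::AAStringSet(
        stats::setNames(unlist(payload$sequences$seq),
                        unlist(payload$sequences$key)))
    membership <- data.frame(
        cluster = as.integer(payload$membership$cluster),
        taxon = as.character(payload$membership$taxon),
        protein = as.character(payload$membership$protein),
        stringsAsFactors = FALSE)
    clusters <- methods::new("ClusterSet", membership = membership,
                             sequences = seqs)
    pr <- payload$profiles
    values <- as.integer(unlist(pr$values))
    if (length(values) != pr$n_taxa * pr$n_clusters)
        stop("corrupt or truncated library file '", path,
             "': profile block has wrong length")
    bits <- matrix(values, nrow = pr$n_taxa, ncol = pr$n_clusters,
                   byrow = TRUE,
                   dimnames = list(unlist(payload$taxa),
                                   unlist(payload$cluster_ids)))
    list(clusters = clusters,
         matrix = methods::new("ProfileMatrix", bits = bits))
}
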