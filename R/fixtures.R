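## random amino-acid sequence, uniform over the 20 standard residues
.randomProtein <- function(len)
    paste(sample(.AA_STANDARD20, len, replace = TRUE), collapse = "")

## substitute each residue with probability `rate` (to a different residue)
.mutateProtein <- function(s, rate) {
    if (rate <= 0) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(v)) < rate)
    for (i in hit)
        v[i] <- sample(setdiff(.AA_STANDARD20, v[i]), 1L)
    paste(v, collapse = "")
}

#' Generate synthetic proteomes with planted homolog families
#'
#' Emulates a set of related proteomes at the scale the pipeline is
#' validated on: `nFamilies` ancestral proteins (uniform-random sequences,
#' lengths drawn from `lengthRange`) are each present in a taxon with
#' probability `presenceProb`; each present copy is an independent
#' per-residue mutation of the ancestor at `mutationRate`. With
#' probability `dupProb` a present copy also gets a within-taxon duplicate
#' differing by exactly one substitution (so the duplicate pair's
#' similarity score is guaranteed >= 0.45). Each taxon additionally
#' carries `nPrivate` fresh random proteins with no homolog anywhere. The
#' same seed yields byte-identical output.
#'
#' Alongside the proteomes the generator emits the ground truth the
#' pipeline should recover: per-protein family labels, the planted
#' duplicate pairs, and the expected post-pipeline incidence matrix. A
#' family forms an expected cluster only when, after duplicate removal, it
#' still has members in >= 2 taxa (families seen in fewer taxa are
#' singletons and are dropped by [buildClusters()]); expected clusters are
#' ordered by the same smallest-member-key rule the pipeline uses.
#'
#' @param nTaxa number of taxa (>= 2), default 6.
#' @param nFamilies number of homolog families (>= 1), default 10.
#' @param presenceProb per-taxon probability a family is present,
#'   default 0.8.
#' @param mutationRate per-residue substitution probability of a family
#'   copy, default 0.05.
#' @param nPrivate private (unrelated) proteins per taxon, default 5.
#' @param dupProb probability a present family copy is duplicated within
#'   its taxon, default 0.2.
#' @param seed integer; fully determines the output.
#' @param dir if non-NULL, write one FASTA per taxon plus truth TSVs here.
#' @param lengthRange ancestral length range, default c(80, 300).
#' @return A list with elements `proteomes` (list of [Proteome-class]),
#'   `truth` (list: `proteins` data.frame with columns taxon, protein,
#'   family, isDuplicate; `duplicates` data.frame of planted duplicate
#'   pairs; `presence` taxa x families 0/1 matrix; `incidence` the
#'   expected [buildProfileMatrix()] output as a plain matrix;
#'   `expectedClusters` list mapping expected cluster column to member
#'   keys), and `files` (paths written, or NULL).
#' @examples
#' fx <- generateFixtures(nTaxa = 3, nFamilies = 4, seed = 1)
#' fx$proteomes[[1]]
#' @export
generateFixtures <- function(nTaxa = 6L, nFamilies = 10L,
                             presenceProb = 0.8, mutationRate = 0.05,
                             nPrivate = 5L, dupProb = 0.2, seed = 1L,
                             dir = NULL, lengthRange = c(80L, 300L)) {
    stopifnot(nTaxa >= 2L, nFamilies >= 1L,
              presenceProb >= 0, presenceProb <= 1,
              mutationRate >= 0, mutationRate <= 1,
              dupProb >= 0, dupProb <= 1, nPrivate >= 0L,
              length(lengthRange) == 2L, lengthRange[1L] >= 1L,
              lengthRange[1L] <= lengthRange[2L])
    withr::with_seed(as.integer(seed), {
        taxa <- sprintf("taxon%02d", seq_len(nTaxa))
        famIds <- sprintf("fam%03d", seq_len(nFamilies))
        ancLen <- sample(lengthRange[1L]:lengthRange[2L], nFamilies,
                         replace = TRUE)
        ancestors <- vapply(ancLen, .randomProtein, "")
        presence <- matrix(0L, nTaxa, nFamilies,
                           dimnames = list(taxa, famIds))
        rows <- list()
        proteomes <- vector("list", nTaxa)
        for (t in seq_len(nTaxa)) {
            seqs <- character(); ids <- character()
            fam <- character(); dup <- logical()
            for (f in seq_len(nFamilies)) {
                if (stats::runif(1L) >= presenceProb) next
                presence[t, f] <- 1L
                copy <- .mutateProtein(ancestors[f], mutationRate)
                seqs <- c(seqs, copy); ids <- c(ids, famIds[f])
                fam <- c(fam, famIds[f]); dup <- c(dup, FALSE)
                if (stats::runif(1L) < dupProb) {
                    pos <- sample.int(nchar(copy), 1L)
                    v <- strsplit(copy, "", fixed = TRUE)[[1L]]
                    v[pos] <- sample(setdiff(.AA_STANDARD20, v[pos]), 1L)
                    seqs <- c(seqs, paste(v, collapse = ""))
                    ids <- c(ids, paste0(famIds[f], "_dup"))
                    fam <- c(fam, famIds[f]); dup <- c(dup, TRUE)
                }
            }
            if (nPrivate > 0L) {
                privLen <- sample(lengthRange[1L]:lengthRange[2L], nPrivate,
                                  replace = TRUE)
                seqs <- c(seqs, vapply(privLen, .randomProtein, ""))
                ids <- c(ids, sprintf("priv%03d", seq_len(nPrivate)))
                fam <- c(fam, rep(NA_character_, nPrivate))
                dup <- c(dup, rep(FALSE, nPrivate))
            }
            if (length(seqs) == 0L) {
                # a taxon with no proteins cannot form a valid Proteome;
                # give it one private protein regardless
                seqs <- .randomProtein(
                    sample(lengthRange[1L]:lengthRange[2L], 1L))
                ids <- "priv000"
                fam <- NA_character_; dup <- FALSE
            }
            names(seqs) <- ids
            proteomes[[t]] <- Proteome(taxa[t], seqs)
            rows[[t]] <- data.frame(taxon = taxa[t], protein = ids,
                                    family = fam, isDuplicate = dup,
                                    stringsAsFactors = FALSE)
        }
        proteins <- do.call(rbind, rows)
        duplicates <- proteins[proteins$isDuplicate, c("taxon", "family")]
        duplicates <- data.frame(
            taxon = duplicates$taxon,
            kept = duplicates$family,
            removed = if (nrow(duplicates))
                paste0(duplicates$family, "_dup") else character(),
            stringsAsFactors = FALSE)
        rownames(duplicates) <- NULL
        # expected clusters: families in >= 2 taxa after dedup, ordered by
        # smallest member key "taxonNN|famFFF" (same rule as buildClusters)
        keep <- which(colSums(presence) >= 2L)
        minKey <- vapply(keep, function(f)
            min(paste(taxa[presence[, f] == 1L], famIds[f], sep = "|")), "")
        keep <- keep[order(minKey)]
        incidence <- presence[, keep, drop = FALSE]
        colnames(incidence) <- if (length(keep))
            paste0("C", seq_along(keep)) else NULL
        expectedClusters <- lapply(keep, function(f)
            sort(paste(taxa[presence[, f] == 1L], famIds[f], sep = "|")))
        names(expectedClusters) <- colnames(incidence)
        files <- NULL
        if (!is.null(dir)) {
            if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
            files <- character()
            for (t in seq_len(nTaxa)) {
                f <- file.path(dir, paste0(taxa[t], ".faa"))
                Biostrings::writeXStringSet(
                    proteinSequences(proteomes[[t]]), f)
                files <- c(files, f)
            }
            tf <- file.path(dir, "truth_proteins.tsv")
            utils::write.table(proteins, tf, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            inc <- file.path(dir, "truth_incidence.tsv")
            utils::write.table(
                data.frame(taxon_id = rownames(incidence), incidence,
                           check.names = FALSE),
                inc, sep = "\t", quote = FALSE, row.names = FALSE)
            files <- c(files, tf, inc)
        }
        list(proteomes = proteomes,
             truth = list(proteins = proteins, duplicates = duplicates,
                          presence = presence, incidence = incidence,
                          expectedClusters = expectedClusters),
             files = files)
    })
}
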