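#' Alignment scoring configuration
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' exact-match prefilter word size used throughout the pipeline. A gap of
#' length L costs `gapOpen + L * gapExtend`. The defaults (BLOSUM62,
#' open 10, extend 1, word size 4) follow BLAST-family conventions; the
#' word size is the exact-match seed length of the candidate-pair
#' prefilter.
#'
#' @param matrix name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`), or a numeric matrix.
#' @param gapOpen nonnegative gap opening penalty.
#' @param gapExtend nonnegative per-residue gap extension penalty.
#' @param k exact-match word size for [candidatePairs()], >= 1.
#' @return A list with elements `matrix` (the resolved numeric matrix),
#'   `matrixName`, `gapOpen`, `gapExtend`, `k`.
#' @examples
#' cfg <- scoringConfig()
#' cfg$matrixName
#' @export
scoringConfig <- function(matrix = "BLOSUM62", gapOpen = 10, gapExtend = 1,
                          k = 4L) {
    if (is.character(matrix)) {
        name <- matrix
        e <- new.env()
        utils::data(list = name, package = "Biostrings", envir = e)
        matrix <- get(name, envir = e)
    } else {
        name <- "custom"
    }
    stopifnot(is.matrix(matrix), gapOpen >= 0, gapExtend >= 0, k >= 1)
    list(matrix = matrix, matrixName = name,
         gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend),
         k = as.integer(k))
}

.asAAString <- function(x) {
    if (methods::is(x, "AAString")) x else Biostrings::AAString(as.character(x))
}

## Vectorised local alignment of patterns against one subject; returns
## columns matchLength (aligned columns incl. gaps), identity (identical
## columns / aligned columns) and rawScore. A pair with no positive-scoring
## local alignment reports matchLength 0, identity 0, rawScore 0.
.alignToSubject <- function(patterns, subject, params) {
    aln <- Biostrings::pairwiseAlignment(
        patterns, subject, type = "local",
        substitutionMatrix = params$matrix,
        gapOpening = params$gapOpen, gapExtension = params$gapExtend)
    len <- Biostrings::nchar(aln)
    sc <- Biostrings::score(aln)
    nm <- Biostrings::nmatch(aln)
    none <- sc <= 0 | len == 0L
    data.frame(
        matchLength = ifelse(none, 0L, len),
        identity    = ifelse(none, 0, nm / pmax(len, 1L)),
        rawScore    = ifelse(none, 0, sc))
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Computes the optimal local alignment under the configured substitution
#' matrix and affine gap penalties and summarises one optimal traceback as
#' the aligned-region length (`matchLength`, counting gap columns), the
#' fractional identity over the aligned region (`identity`, in [0, 1]) and
#' the raw alignment score. When no local alignment attains a positive
#' score, all three are 0.
#'
#' @param a,b amino-acid sequences (character or `AAString`), nonempty.
#' @param params a [scoringConfig()].
#' @return A list with numeric elements `matchLength`, `identity`,
#'   `rawScore`.
#' @examples
#' smithWaterman("MKV", "MKV")
#' smithWaterman("AAAA", "CCCC")  # no positive-scoring alignment
#' @export
smithWaterman <- function(a, b, params = scoringConfig()) {
    a <- as.character(a); b <- as.character(b)
    stopifnot(nzchar(a), nzchar(b))
    r <- .alignToSubject(Biostrings::AAStringSet(a), .asAAString(b), params)
    list(matchLength = as.integer(r$matchLength[1L]),
         identity = r$identity[1L], rawScore = r$rawScore[1L])
}

#' Pairwise similarity score from a local alignment
#'
#' The score is `matchLength * identity / (nchar(reference) +
#' nchar(candidate))`: aligned-region length times fractional identity,
#' divided by the sum of the two full sequence lengths. It ranges over
#' [0, 0.5]; the maximum 0.5 is attained exactly when the two sequences are
#' an exact match (a full-length alignment at identity 1 of equal-length
#' sequences). Including both lengths in the denominator keeps a large
#' length difference from inflating the score. Scores >= 0.45 flag
#' within-proteome duplicates; scores > 0.2 define cluster membership when
#' profiling a new taxon.
#'
#' @param reference,candidate the two sequences (character, `AAString` or
#'   [Proteome-class] members) the alignment was computed for.
#' @param aln result of [smithWaterman()] for this pair.
#' @return A single numeric in [0, 0.5].
#' @examples
#' aln <- smithWaterman("MKVLT", "MKVLT")
#' similarityScore("MKVLT", "MKVLT", aln)  # 0.5
#' @export
similarityScore <- function(reference, candidate, aln) {
    la <- nchar(as.character(reference))
    lb <- nchar(as.character(candidate))
    stopifnot(la >= 1L, lb >= 1L)
    aln$matchLength * aln$identity / (la + lb)
}

## score for precomputed lengths, vectorised
.simScore <- function(matchLength, identity, lenA, lenB)
    matchLength * identity / (lenA + lenB)

## unique k-mers of one sequence string
.kmers <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), k:n))
}

#' Candidate pairs sharing an exact k-mer
#'
#' The clustering prefilter: returns exactly the unordered pairs of
#' sequences that share at least one exact common substring of length `k`,
#' found with a k-mer inverted index rather than all-pairs comparison. Any
#' pair whose alignment contains a gapless identical run of length >= `k`
#' shares such a word, so the output is a superset of the homolog pairs the
#' aligner could link; increasing `k` only removes pairs.
#'
#' @param seqs named character vector or named `AAStringSet`.
#' @param k word size, >= 1 (default 4).
#' @return data.frame with character columns `i`, `j` (names of the two
#'   sequences, `i` before `j` in input order), one row per pair.
#' @examples
#' candidatePairs(c(a = "MKVLTA", b = "WMKVLS", c = "PPPPPP"), k = 4)
#' @export
candidatePairs <- function(seqs, k = 4L) {
    k <- as.integer(k)
    stopifnot(k >= 1L)
    s <- as.character(seqs)
    nms <- names(seqs)
    if (is.null(nms)) nms <- as.character(seq_along(s))
    idx <- .pairsSharingKmer(s, k)
    data.frame(i = nms[idx[, 1L]], j = nms[idx[, 2L]],
               stringsAsFactors = FALSE)
}

## integer-index pairs (col1 < col2) of sequences sharing a k-mer
.pairsSharingKmer <- function(s, k) {
    km <- lapply(s, .kmers, k = k)
    id <- rep.int(seq_along(s), lengths(km))
    buckets <- split(id, unlist(km, use.names = FALSE))
    pairs <- lapply(buckets, function(b) {
        if (length(b) < 2L) return(NULL)
        b <- sort.int(b)
        cbind(rep(b, times = rev(seq_along(b)) - 1L),
              b[sequence(rev(seq_along(b)) - 1L, from = seq_along(b) + 1L)])
    })
    out <- do.call(rbind, pairs)
    if (is.null(out)) return(matrix(integer(), ncol = 2L))
    out <- unique(out)
    out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

## cross-set variant: pairs (i in a, j in b) sharing a k-mer
.crossPairsSharingKmer <- function(a, b, k) {
    kmB <- lapply(b, .kmers, k = k)
    idB <- rep.int(seq_along(b), lengths(kmB))
    index <- split(idB, unlist(kmB, use.names = FALSE))
    rows <- vector("list", length(a))
    for (i in seq_along(a)) {
        ka <- .kmers(a[[i]], k)
        hits <- unlist(index[ka], use.names = FALSE)
        if (length(hits))
            rows[[i]] <- cbind(i, sort.int(unique(hits)))
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) matrix(integer(), ncol = 2L) else out
}

## Align an explicit list of index pairs over a common sequence vector,
## batching all patterns that share a subject into one vectorised call.
## Returns data.frame(i, j, matchLength, identity, rawScore).
.alignPairs <- function(seqs, pairs, params) {
    if (nrow(pairs) == 0L)
        return(data.frame(i = integer(), j = integer(),
                          matchLength = integer(), identity = numeric(),
                          rawScore = numeric()))
    sset <- Biostrings::AAStringSet(seqs)
    res <- vector("list", length(seqs))
    for (jj in sort.int(unique(pairs[, 2L]))) {
        ii <- pairs[pairs[, 2L] == jj, 1L]
        r <- .alignToSubject(sset[ii], sset[[jj]], params)
        res[[jj]] <- cbind(i = ii, j = jj, r)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
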