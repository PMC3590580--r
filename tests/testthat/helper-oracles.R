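# Independent oracles and small generators used across the test files.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")

randProtein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

substituteAt <- function(s, positions) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (i in positions) v[i] <- sample(setdiff(AA20, v[i]), 1L)
    paste(v, collapse = "")
}

blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})

# Unoptimized full Gotoh dynamic program for optimal local alignment score
# under affine gaps (a gap of length L costs open + L * ext). Independent of
# the package's alignment path; intended for short sequences only.
oracleLocalScore <- function(a, b, mat = blosum62, open = 10, ext = 1) {
    A <- strsplit(a, "", fixed = TRUE)[[1L]]
    B <- strsplit(b, "", fixed = TRUE)[[1L]]
    n <- length(A); m <- length(B)
    H <- matrix(0, n + 1L, m + 1L)
    E <- matrix(-Inf, n + 1L, m + 1L)
    F <- matrix(-Inf, n + 1L, m + 1L)
    best <- 0
    for (i in seq_len(n) + 1L) {
        for (j in seq_len(m) + 1L) {
            E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
            F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
            H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[A[i - 1L], B[j - 1L]],
                           E[i, j], F[i, j])
            if (H[i, j] > best) best <- H[i, j]
        }
    }
    best
}

# Random edge-weighted binary tree and its additive (path-length) matrix.
randomAdditiveMatrix <- function(nLeaves) {
    tr <- ape::rtree(nLeaves)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    list(tree = tr, d = stats::cophenetic(tr))
}

# Quadratic all-pairs scan for shared k-mers (prefilter oracle).
bruteForceSharedKmerPairs <- function(seqs, k) {
    nms <- names(seqs)
    km <- lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < k) character() else unique(substring(s, 1:(n - k + 1), k:n))
    })
    out <- list()
    for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
        if (i < j && length(intersect(km[[i]], km[[j]])))
            out[[length(out) + 1L]] <- c(nms[i], nms[j])
    }
    if (length(out)) {
        m <- do.call(rbind, out)
        data.frame(i = m[, 1L], j = m[, 2L], stringsAsFactors = FALSE)
    } else data.frame(i = character(), j = character())
}

# Hand-count Jaccard/Euclidean components on two binary rows.
countPQR <- function(x, y) {
    list(p = sum(x == 1 & y == 1), q = sum(x == 1 & y == 0),
         r = sum(x == 0 & y == 1))
}
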