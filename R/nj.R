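#' Neighbor-joining dendrogram from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining: iteratively join the pair
#' minimizing the Q-criterion, assign branch lengths by the standard
#' two-point formulas and reduce the matrix. The result is an unrooted
#' tree represented with a basal trifurcation, consistent on additive
#' matrices (the true topology and branch lengths are recovered exactly).
#' Negative branch lengths, which NJ can produce on non-additive input,
#' are clamped to 0 and the total clamped deficit is logged; no length is
#' transferred to sibling edges.
#'
#' @param d a [stats::dist] or symmetric zero-diagonal matrix with >= 3
#'   labelled taxa.
#' @return An unrooted [ape::phylo] tree whose tip labels are the taxon
#'   ids.
#' @seealso [writeNewick()], [jaccardDistance()]
#' @examples
#' m <- matrix(c(0,2,4, 2,0,4, 4,4,0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighborJoin(m)
#' @export
neighborJoin <- function(d) {
    if (is.matrix(d)) {
        if (!isSymmetric(unname(d)) || any(diag(d) != 0))
            stop("distance matrix must be symmetric with zero diagonal")
        d <- stats::as.dist(d)
    }
    if (!inherits(d, "dist"))
        stop("'d' must be a dist object or a symmetric matrix")
    n <- attr(d, "Size")
    if (n < 3L)
        stop("neighbor joining needs at least 3 taxa; for 2 taxa the tree ",
             "is a single edge of length d(1,2)")
    tree <- ape::nj(d)
    neg <- tree$edge.length < 0
    if (any(neg)) {
        message("neighborJoin: clamped ", sum(neg),
                " negative branch length(s) to 0 (total deficit ",
                format(-sum(tree$edge.length[neg]), digits = 6), ")")
        tree$edge.length[neg] <- 0
    }
    tree
}
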