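# Shared small library built once per file from planted fixtures.
insertionLib <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            fx <- generateFixtures(nTaxa = 6, nFamilies = 8, seed = 701)
            deduped <- suppressMessages(lapply(fx$proteomes, dedupeProteome))
            cl <- buildClusters(deduped)
            pm <- buildProfileMatrix(cl, deduped)
            cache <<- list(fx = fx, proteomes = deduped, clusters = cl,
                           matrix = pm)
        }
        cache
    }
})

test_that("re-profiling a library taxon reproduces its library row", {
    lib <- insertionLib()
    for (t in c(2L, 5L)) {
        p <- lib$proteomes[[t]]
        copy <- Proteome(paste0(taxonId(p), "_copy"),
                         proteinSequences(p))
        pr <- profileNewTaxon(copy, lib$clusters)
        expect_identical(unname(profileBits(pr)),
                         unname(profileBits(lib$matrix)[taxonId(p), ]))
    }
})

test_that("an unrelated random proteome gets an all-zero profile", {
    lib <- insertionLib()
    set.seed(702)
    p <- Proteome("stranger",
                  setNames(vapply(1:8, function(i) randProtein(150), ""),
                           paste0("p", 1:8)))
    pr <- profileNewTaxon(p, lib$clusters)
    expect_identical(sum(profileBits(pr)), 0L)
})

test_that("a chimeric protein sets the bits of both parent clusters", {
    set.seed(703)
    f1 <- randProtein(120); f2 <- randProtein(120)
    ps <- lapply(1:3, function(t)
        Proteome(paste0("t", t), setNames(c(f1, f2), c("a", "b"))))
    cl <- buildClusters(ps)
    expect_identical(nClusters(cl), 2L)
    chimera <- Proteome("chi", c(ab = paste0(f1, f2)))
    pr <- profileNewTaxon(chimera, cl)
    # score vs a member: 120 * 1 / (240 + 120) = 1/3 > 0.2 for both halves
    expect_identical(unname(profileBits(pr)), c(1L, 1L))
})

test_that("membership uses a strictly-greater comparison", {
    # one cluster of two identical 100-mers; a candidate sharing exactly
    # 40 leading residues scores 40/200 = 0.2, which must NOT qualify
    set.seed(704)
    s <- randProtein(100)
    ps <- lapply(1:2, function(t) Proteome(paste0("t", t), c(a = s)))
    cl <- buildClusters(ps)
    candidate <- paste0(substr(s, 1, 40), randProtein(60))
    sc <- similarityScore(candidate, s, smithWaterman(candidate, s))
    if (identical(sc, 0.2)) {
        pr <- profileNewTaxon(Proteome("edge", c(x = candidate)), cl)
        expect_identical(sum(profileBits(pr)), 0L)
    }
    # and a shade above the cutoff qualifies
    candidate2 <- paste0(substr(s, 1, 45), randProtein(55))
    sc2 <- similarityScore(candidate2, s, smithWaterman(candidate2, s))
    expect_gt(sc2, 0.2)
    pr2 <- profileNewTaxon(Proteome("edge2", c(x = candidate2)), cl)
    expect_identical(sum(profileBits(pr2)), 1L)
})

test_that("Pearson correlation against the library behaves as closed form", {
    bits <- matrix(c(1L, 1L, 0L, 0L,
                     1L, 0L, 1L, 0L,
                     0L, 0L, 1L, 1L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("t1", "t2", "t3"), paste0("C", 1:4)))
    lib <- methods::new("ProfileMatrix", bits = bits)
    mk <- function(v) methods::new("BinaryProfile", taxon = "new",
                                   bits = setNames(as.integer(v),
                                                   paste0("C", 1:4)))
    r <- correlateProfile(mk(c(1, 1, 0, 0)), lib)
    expect_equal(unname(r@coefficients["t1"]), 1)   # identical row
    expect_equal(unname(r@coefficients["t3"]), -1)  # bitwise complement
    expect_equal(unname(r@coefficients["t2"]), 0)   # (1,1,0,0) vs (1,0,1,0)
    expect_identical(r@bestMatch, "t1")
    expect_true(r@accepted)
    expect_true(all(abs(r@coefficients) <= 1 + 1e-12))
})

test_that("zero-variance rows correlate as 0 with a warning", {
    bits <- matrix(c(1L, 1L, 1L, 1L,
                     1L, 0L, 1L, 0L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("flat", "ok"), paste0("C", 1:4)))
    lib <- methods::new("ProfileMatrix", bits = bits)
    pr <- methods::new("BinaryProfile", taxon = "new",
                       bits = setNames(c(1L, 0L, 1L, 0L), paste0("C", 1:4)))
    expect_warning(r <- correlateProfile(pr, lib), "zero-variance")
    expect_equal(unname(r@coefficients["flat"]), 0)
    expect_equal(unname(r@coefficients["ok"]), 1)
})

test_that("profile/library length mismatch names both lengths", {
    lib <- insertionLib()
    pr <- methods::new("BinaryProfile", taxon = "new", bits = c(C1 = 1L))
    expect_error(correlateProfile(pr, lib$matrix), "1.*does not match")
})

test_that("inserting a copy of a library taxon places it as a sister", {
    lib <- insertionLib()
    # taxon04 has a mixed presence row, so its Pearson coefficient is defined
    target <- lib$proteomes[[4]]
    copy <- Proteome("insert_me", proteinSequences(target))
    pr <- profileNewTaxon(copy, lib$clusters)
    res <- suppressWarnings(augmentTree(lib$matrix, list(pr)))
    rep3 <- res$reports[[1]]
    expect_equal(rep3@bestValue, 1)
    expect_identical(rep3@bestMatch, taxonId(target))
    expect_true(rep3@accepted)
    expect_identical(res$accepted, "insert_me")
    # sister placement: shares its parent node with the original leaf
    tr <- res$tree
    tips <- match(c("insert_me", taxonId(target)), tr$tip.label)
    parents <- tr$edge[match(tips, tr$edge[, 2]), 1]
    expect_identical(parents[1], parents[2])
    expect_lt(stats::cophenetic(tr)["insert_me", taxonId(target)], 1e-9)
})

test_that("profiles below the threshold are rejected, tree unchanged", {
    lib <- insertionLib()
    set.seed(705)
    base <- suppressMessages(neighborJoin(jaccardDistance(lib$matrix)))
    pr <- methods::new("BinaryProfile", taxon = "noise",
                       bits = setNames(
                           as.integer(rbinom(ncol(profileBits(lib$matrix)),
                                             1, 0.5)),
                           colnames(profileBits(lib$matrix))))
    r <- suppressWarnings(correlateProfile(pr, lib$matrix))
    if (r@bestValue < 0.5) {
        res <- suppressWarnings(suppressMessages(
            augmentTree(lib$matrix, list(pr))))
        expect_length(res$accepted, 0)
        expect_false(res$reports[[1]]@accepted)
        expect_equal(as.numeric(ape::dist.topo(res$tree, base)), 0)
        expect_false("noise" %in% res$tree$tip.label)
    } else {
        skip("random profile happened to correlate above threshold")
    }
})

test_that("a batch of related taxa is accepted and forms a clade", {
    lib <- insertionLib()
    # three newly sequenced taxa whose gene content matches taxon04's row
    row <- profileBits(lib$matrix)["taxon04", ]
    profs <- lapply(1:3, function(i)
        methods::new("BinaryProfile", taxon = paste0("new", i), bits = row))
    res <- suppressWarnings(augmentTree(lib$matrix, profs))
    expect_identical(res$accepted, c("new1", "new2", "new3"))
    expect_true(all(vapply(res$reports, methods::slot, TRUE, "accepted")))
    # the inserted taxa plus their anchor are mutually nearest in the tree
    cp <- stats::cophenetic(res$tree)
    grp <- c("taxon04", "new1", "new2", "new3")
    others <- setdiff(res$tree$tip.label, grp)
    expect_lt(max(cp[grp, grp]), min(cp[grp, others]))
})

test_that("an empty proteome cannot be profiled", {
    lib <- insertionLib()
    expect_error(Proteome("empty", character()),
                 "at least one sequence|invalid")
})
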