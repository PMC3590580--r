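writeFasta <- function(lines) {
    f <- tempfile(fileext = ".faa")
    writeLines(lines, f)
    f
}

test_that("FASTA reading preserves entries and normalizes sequences", {
    f <- writeFasta(c(">p1 desc", "mkvlt", ">p2", "GGH", "ARN", ">p3", "WWW"))
    p <- readProteome(f, "tx")
    expect_s4_class(p, "Proteome")
    expect_identical(length(p), 3L)
    expect_identical(taxonId(p), "tx")
    expect_identical(names(proteinSequences(p)), c("p1", "p2", "p3"))
    expect_identical(as.character(proteinSequences(p))[["p1"]], "MKVLT")
    expect_identical(as.character(proteinSequences(p))[["p2"]], "GGHARN")
})

test_that("non-standard residues are mapped to X with a warning", {
    f <- writeFasta(c(">p1", "MKBLZU", ">p2", "ARNDC"))
    expect_warning(p <- readProteome(f, "tx"), "non-standard")
    expect_identical(as.character(proteinSequences(p))[["p1"]], "MKXLXX")
    expect_identical(as.character(proteinSequences(p))[["p2"]], "ARNDC")
})

test_that("stop characters: trailing stripped, internal rejected", {
    f <- writeFasta(c(">p1", "MKVLT*"))
    p <- readProteome(f, "tx")
    expect_identical(as.character(proteinSequences(p))[["p1"]], "MKVLT")
    f2 <- writeFasta(c(">ok", "ARN", ">bad", "MKV*LT"))
    expect_error(readProteome(f2, "tx"), "bad")
})

test_that("degenerate FASTA input is rejected with informative errors", {
    f <- writeFasta(character())
    expect_error(readProteome(f, "tx"), "no sequences")
    f2 <- writeFasta(c(">p1", "MKV", ">empty", "", ">p3", "ARN"))
    expect_error(readProteome(f2, "tx"), "empty")
    f3 <- writeFasta(c(">p1", "MKV", ">p1", "ARN"))
    expect_error(readProteome(f3, "tx"), "duplicate")
    expect_error(readProteome(tempfile(), "tx"), "no such file")
})

test_that("Newick output parses and round-trips topology and lengths", {
    two <- ape::read.tree(text = "(A:0.1,B:0.2);")
    f <- tempfile(fileext = ".nwk")
    writeNewick(two, f)
    back <- ape::read.tree(f)
    expect_setequal(back$tip.label, c("A", "B"))
    expect_equal(sort(back$edge.length), c(0.1, 0.2))

    # 4-leaf NJ output: unrooted with a trifurcating root, exact round trip
    oracle <- randomAdditiveMatrix(4)
    tr <- neighborJoin(oracle$d)
    writeNewick(tr, f)
    back <- ape::read.tree(f)
    expect_identical(back$Nnode, 2L)  # trifurcation at the root of 4 leaves
    expect_equal(unname(table(back$edge[, 1])[as.character(5L)]), 3)
    expect_equal(as.numeric(ape::dist.topo(back, tr)), 0,
                 ignore_attr = TRUE)
    expect_equal(stats::cophenetic(back)[rownames(oracle$d), colnames(oracle$d)],
                 oracle$d, tolerance = 1e-6)
})

test_that("Newick labels outside the safe alphabet are sanitized", {
    tr <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.3);")
    tr$tip.label <- c("pl asm:1", "ok_label", "x|y")
    f <- tempfile(fileext = ".nwk")
    expect_message(writeNewick(tr, f), "sanitized")
    back <- ape::read.tree(f)
    expect_setequal(back$tip.label, c("pl_asm_1", "ok_label", "x_y"))
})

test_that("trees with fewer than 2 leaves are refused", {
    tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
    tr1 <- ape::keep.tip(tr, "A")
    expect_error(writeNewick(tr1, tempfile()), "2 leaves")
})

buildTinyLibrary <- function(seed = 11) {
    set.seed(seed)
    fx <- generateFixtures(nTaxa = 4, nFamilies = 6, seed = seed)
    deduped <- suppressMessages(lapply(fx$proteomes, dedupeProteome))
    cl <- buildClusters(deduped)
    pm <- suppressWarnings(buildProfileMatrix(cl, deduped))
    list(clusters = cl, matrix = pm)
}

test_that("library persistence round-trips losslessly and is byte-stable", {
    lib <- buildTinyLibrary()
    f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
    saveLibrary(lib$clusters, lib$matrix, f1)
    saveLibrary(lib$clusters, lib$matrix, f2)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    back <- loadLibrary(f1)
    expect_identical(clusterMembership(back$clusters),
                     clusterMembership(lib$clusters))
    expect_identical(as.character(proteinSequences(back$clusters)),
                     as.character(proteinSequences(lib$clusters)))
    expect_identical(profileBits(back$matrix), profileBits(lib$matrix))
    expect_identical(ncol(profileBits(back$matrix)), nClusters(lib$clusters))
})

test_that("library loading validates format, version and integrity", {
    lib <- buildTinyLibrary()
    f <- tempfile(fileext = ".json")
    saveLibrary(lib$clusters, lib$matrix, f)

    # truncation
    txt <- readChar(f, file.size(f))
    ftrunc <- tempfile()
    writeChar(substr(txt, 1, nchar(txt) %/% 2), ftrunc, eos = NULL)
    expect_error(loadLibrary(ftrunc), "corrupt|truncated")

    # version bump
    payload <- jsonlite::fromJSON(f, simplifyVector = TRUE)
    payload$version <- 99L
    fver <- tempfile()
    jsonlite::write_json(payload, fver, auto_unbox = TRUE)
    expect_error(loadLibrary(fver), "version mismatch")

    # foreign JSON
    falien <- tempfile()
    jsonlite::write_json(list(hello = "world"), falien, auto_unbox = TRUE)
    expect_error(loadLibrary(falien), "not a")
})

test_that("saving a library with zero taxa is refused", {
    lib <- buildTinyLibrary()
    empty <- methods::new("ProfileMatrix",
        bits = matrix(integer(), nrow = 0, ncol = nClusters(lib$clusters),
                      dimnames = list(NULL, paste0("C", seq_len(nClusters(lib$clusters))))))
    expect_error(saveLibrary(lib$clusters, empty, tempfile()), "zero taxa")
})
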