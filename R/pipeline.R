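.writeManifest <- function(path, command, params, inputs) {
    digests <- if (length(inputs) && all(file.exists(inputs)))
        as.list(tools::md5sum(inputs)) else NULL
    jsonlite::write_json(
        list(command = command,
             package = "ProfileTree",
             package_version = as.character(utils::packageVersion("ProfileTree")),
             r_version = paste(R.version$major, R.version$minor, sep = "."),
             parameters = params,
             input_md5 = digests),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Run the full build pipeline
#'
#' fasta -> dedup -> homolog clustering -> binary profiles -> distance ->
#' neighbor joining. Writes `tree.nwk`, the persisted correlation filter
#' library (`library.json`), the cluster table (`clusters.tsv`), the
#' profile matrix (`matrix.tsv`), the distance matrix (`distance.phy`) and
#' a machine-readable run manifest (`manifest.json`, parameters + input
#' digests; no timestamps, so reruns on identical input are byte-identical).
#'
#' @param fastaFiles character vector of per-taxon FASTA paths (>= 3), or
#'   NULL when `proteomes` is given.
#' @param taxonIds taxon ids for `fastaFiles`; defaults to file base names.
#' @param proteomes alternatively, a list of [Proteome-class] objects.
#' @param outDir output directory (created if needed).
#' @param metric `"jaccard"` (default) or `"euclidean"`.
#' @param dedupThreshold duplicate score cutoff, default 0.45.
#' @param minIdentity,minAlnLen,minCoverage homology edge criteria, see
#'   [buildClusters()].
#' @param params a [scoringConfig()].
#' @return Invisibly, a list with the in-memory objects (`proteomes`,
#'   `clusters`, `matrix`, `dist`, `tree`) and the written `paths`.
#' @seealso [runInsert()], [generateFixtures()]
#' @export
runBuild <- function(fastaFiles = NULL, taxonIds = NULL, proteomes = NULL,
                     outDir, metric = c("jaccard", "euclidean"),
                     dedupThreshold = 0.45, minIdentity = 0.40,
                     minAlnLen = 20L, minCoverage = 0.60,
                     params = scoringConfig()) {
    metric <- match.arg(metric)
    if (is.null(proteomes)) {
        stopifnot(length(fastaFiles) >= 3L)
        if (is.null(taxonIds))
            taxonIds <- tools::file_path_sans_ext(basename(fastaFiles))
        proteomes <- unname(Map(readProteome, fastaFiles, taxonIds))
    }
    if (length(proteomes) < 3L)
        stop("tree construction needs at least 3 proteomes")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    deduped <- lapply(proteomes, dedupeProteome, threshold = dedupThreshold,
                      params = params)
    clusters <- buildClusters(deduped, params = params,
                              minIdentity = minIdentity,
                              minAlnLen = minAlnLen,
                              minCoverage = minCoverage)
    pm <- buildProfileMatrix(clusters, deduped)
    d <- switch(metric, jaccard = jaccardDistance(pm),
                euclidean = euclideanDistance(pm))
    tree <- neighborJoin(d)
    paths <- c(tree = file.path(outDir, "tree.nwk"),
               library = file.path(outDir, "library.json"),
               clusters = file.path(outDir, "clusters.tsv"),
               matrix = file.path(outDir, "matrix.tsv"),
               dist = file.path(outDir, "distance.phy"),
               manifest = file.path(outDir, "manifest.json"))
    writeNewick(tree, paths[["tree"]])
    saveLibrary(clusters, pm, paths[["library"]])
    writeClusterTable(clusters, paths[["clusters"]])
    writeProfileMatrix(pm, paths[["matrix"]])
    writeDistanceMatrix(d, paths[["dist"]], format = "phylip")
    .writeManifest(paths[["manifest"]], "build",
                   list(metric = metric, dedupThreshold = dedupThreshold,
                        minIdentity = minIdentity, minAlnLen = minAlnLen,
                        minCoverage = minCoverage,
                        matrix = params$matrixName, gapOpen = params$gapOpen,
                        gapExtend = params$gapExtend, k = params$k),
                   if (is.null(fastaFiles)) character() else fastaFiles)
    invisible(list(proteomes = deduped, clusters = clusters, matrix = pm,
                   dist = d, tree = tree, paths = paths))
}

#' Insert new taxa into a saved dendrogram library
#'
#' Loads the persisted correlation filter library, profiles each new
#' proteome against its clusters (membership score > 0.2 by default),
#' correlates against the library profiles, and rebuilds the dendrogram
#' with every accepted taxon appended (decisions are taken against the
#' original library; accepted rows are appended as one batch). Writes
#' `augmented.nwk`, a per-taxon `report.tsv` (best match, coefficient,
#' decision) and `manifest.json`.
#'
#' @param libraryFile path to a library written by [saveLibrary()].
#' @param fastaFiles FASTA paths of the new proteomes, or NULL when
#'   `proteomes` is given.
#' @param taxonIds taxon ids for `fastaFiles`; defaults to base names.
#' @param proteomes alternatively, a list of [Proteome-class] objects.
#' @param outDir output directory.
#' @param metric `"jaccard"` (default) or `"euclidean"`.
#' @param threshold correlation acceptance threshold, default 0.5.
#' @param membershipThreshold cluster membership score cutoff, default 0.2.
#' @param params a [scoringConfig()].
#' @return Invisibly, the [augmentTree()] result plus `profiles`, a
#'   `report` data.frame and the written `paths`.
#' @export
runInsert <- function(libraryFile, fastaFiles = NULL, taxonIds = NULL,
                      proteomes = NULL, outDir,
                      metric = c("jaccard", "euclidean"), threshold = 0.5,
                      membershipThreshold = 0.2, params = scoringConfig()) {
    metric <- match.arg(metric)
    lib <- loadLibrary(libraryFile)
    if (is.null(proteomes)) {
        stopifnot(length(fastaFiles) >= 1L)
        if (is.null(taxonIds))
            taxonIds <- tools::file_path_sans_ext(basename(fastaFiles))
        proteomes <- unname(Map(readProteome, fastaFiles, taxonIds))
    }
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    profiles <- lapply(proteomes, profileNewTaxon, clusters = lib$clusters,
                       params = params,
                       membershipThreshold = membershipThreshold)
    res <- augmentTree(lib$matrix, profiles, metric = metric,
                       threshold = threshold)
    report <- data.frame(
        taxon_id = vapply(res$reports, methods::slot, "", "newTaxon"),
        best_match = vapply(res$reports, methods::slot, "", "bestMatch"),
        best_correlation = vapply(res$reports, methods::slot, 0, "bestValue"),
        accepted = vapply(res$reports, methods::slot, TRUE, "accepted"),
        threshold = threshold)
    paths <- c(tree = file.path(outDir, "augmented.nwk"),
               report = file.path(outDir, "report.tsv"),
               manifest = file.path(outDir, "manifest.json"))
    writeNewick(res$tree, paths[["tree"]])
    utils::write.table(report, paths[["report"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .writeManifest(paths[["manifest"]], "insert",
                   list(metric = metric, threshold = threshold,
                        membershipThreshold = membershipThreshold,
                        matrix = params$matrixName, gapOpen = params$gapOpen,
                        gapExtend = params$gapExtend, k = params$k),
                   c(libraryFile,
                     if (is.null(fastaFiles)) character() else fastaFiles))
    invisible(c(res, list(profiles = profiles, report = report,
                          paths = paths)))
}
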