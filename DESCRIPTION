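Package: ProfileTree
Title: Whole-Proteome Presence/Absence Profiling and Dendrogram Construction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters homologous proteins across many proteomes with
    seeded Smith-Waterman local alignment (k-mer exact-match prefiltering),
    encodes each taxon as a binary cluster presence/absence profile, builds
    neighbor-joining dendrograms under Jaccard or Euclidean distances, and
    places new taxa into an existing dendrogram through a Pearson
    correlation filter library without re-clustering. Includes a synthetic
    proteome generator with planted homolog families for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Phylogenetics, Clustering, Alignment, ComparativeGenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
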