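Package: zooregions
Title: Temporal Dynamics of Zoogeographical Regions from Phylogenies and
    Fossils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the temporal evolution of zoogeographical regions
    from extant assemblages and fossil occurrences. Provides Simpson
    (turnover-only) species-level and phylogenetic beta dissimilarity,
    slicing of dated phylogenies at arbitrary phylogenetic depths with
    collapse of descendant leaves into crossing lineages, hierarchical
    regionalization with explained-dissimilarity and silhouette cut
    selection, NMDS ordination with Procrustes trajectory analysis and
    Mantel permutation tests, a fossil-occurrence cleaning and interval
    binning pipeline, and a synthetic-data generator with planted regional
    structure for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    cluster,
    igraph,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    mclust,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
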