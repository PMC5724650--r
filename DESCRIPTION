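Package: treeislands
Title: Exploration of Landscapes of Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps collections of rooted, labelled phylogenetic trees into
    metric vector spaces, computes pairwise tree distances under several
    metrics (the Kendall-Colijn lambda-blended metric, Robinson-Foulds,
    Kuhner-Felsenstein branch score, Steel-Penny path difference and its
    l1 variant, Abouheif's dissimilarity, sum of direct descendants),
    projects the resulting landscape into low-dimensional Euclidean space
    by metric multidimensional scaling with Cailliez correction, detects
    clusters of similar topologies ("tree islands") by hierarchical
    clustering, and summarises each island by its geometric median tree.
    Includes a generator of random and island-structured tree sets with
    known ground truth, and a command-line front end chaining the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    ade4,
    mclust,
    igraph,
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
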