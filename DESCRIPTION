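Package: jointclust
Title: Simultaneous Clustering of Multiple Weighted Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects gene modules supported simultaneously by several weighted
    networks defined over one common gene set, such as coexpression networks
    built from expression profiles and physical interaction networks.  Modules
    are found by recursively removing approximate sparsest cuts (spectral sweep
    cuts with flow-based refinement) that fall below graph-specific conductance
    thresholds, with a mixture-graph scaling heuristic that interpolates from
    the sum of the networks towards the individual networks; the resulting
    clustering tree is parsed into final clusters by a dynamic program that
    maximises summed min-modularity across networks.  Ships a planted-partition
    multi-graph simulator with pair-counting Jaccard evaluation, single-tree
    and coassociation consensus baselines, and hypergeometric gene-set
    enrichment evaluation of clusters with Bonferroni control.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
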