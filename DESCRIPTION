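Package: crosspath
Title: Shared Pathway and Common Module Discovery Across Related Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies biological pathways and network modules shared by a
    group of related diseases by combining susceptibility gene panels with a
    protein-protein interaction network. Implements random-walk-with-restart
    expansion of under-annotated gene panels, a permutation test for the
    significance of the panels' common genes, construction of the common-gene
    first-neighbor network (CFNN), two-sided hypergeometric pathway enrichment
    with Benjamini-Hochberg correction, cosine-similarity hierarchical
    clustering of enriched pathways with common-module extraction, and a
    permutation test for differentially expressed multi-protein pathway
    components. Ships a synthetic-data generator with planted ground truth so
    the whole pipeline is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
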