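Package: grnprune
Title: Distance-Based Gene Regulatory Networks and Expression-Driven Pruning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds reference gene regulatory networks by assigning ChIP-Seq
    derived transcription factor binding sites to genes within a distance of
    the transcription start site, then prunes unlikely regulators per gene
    using random-forest importance scores restricted to the pre-assigned
    candidates with a dynamic fraction-of-maximum relevance cutoff. Includes
    validation tools (regulator-set connectance against TF-TF interaction
    networks, co-expression of co-regulated gene pairs, edge-set
    conservation), ego and gene-list subnetwork extraction, a synthetic-data
    generator with known ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    randomForest,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
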