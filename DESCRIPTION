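Package: gsear
Title: Interaction-Based Refinement of Gene Set Enrichment Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weighted running-sum gene set enrichment analysis (GSEA) with
    permutation-based empirical p-values and leading-edge extraction,
    followed by Apriori mining of frequent signed interaction chains among
    leading-edge genes. Frequent chains are scored by the Euclidean norm of
    the statistic d = delta M, the product of the chain's log2 fold-change
    vector with its signed correlation matrix, and ranked within each chain
    cardinality. Includes readers for expression tables, GMT and KEGG-style
    hierarchical gene set collections and signed functional-interaction
    networks, a TPM normalisation and ranking pipeline, and a seeded
    synthetic-data generator with planted pathways and chains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
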