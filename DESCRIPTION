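Package: coexmod
Title: Co-Expression Network Module Extraction and Border-Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs gene co-expression networks from microarray expression
    matrices using a shifting-and-scaling invariant similarity measure, extracts
    co-expressed modules by iterative threshold decrement with formal core-gene
    selection, and marks low-connectivity border genes. Border genes are ranked
    by differential-expression variance and prioritized through Gene Ontology
    Lin semantic similarity (information content over a user-supplied OBO
    ontology and GAF annotations). Modules are validated with exact
    hypergeometric enrichment and Benjamini-Hochberg false discovery rates.
    Includes a synthetic-data generator producing planted affine-pattern
    modules, class-structured samples, and toy ontologies for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
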