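Package: aakmer
Title: Alignment-Free Protein Search with an Amino Acid 7-mer Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a persistent, queryable index of amino-acid 7-mers over a
    protein collection using three logical key-value stores (k-mer store,
    hash-consed combination store, protein store), and searches it by exact
    shared-k-mer counting with optional Smith-Waterman refinement and bit
    scores. Supports protein, six-frame-translated DNA, and short-read
    queries; exposes an opened database as an HTTP microservice with a
    matching remote client; includes a synthetic protein-family generator and
    a homology-group ROC/precision-recall benchmark, plus downstream report
    writers (GFF3 genome annotation, antimicrobial-resistance gene tables,
    annotation-feature profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    curl,
    data.table,
    digest,
    httpuv,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    callr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
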