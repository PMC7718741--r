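Package: selwide
Title: Genome-Wide Positive Selection Scans with Codon Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens directories of codon-aligned ortholog alignments for
    positive selection against a species tree. Alignments are admitted by
    configurable taxon-count filters, the species tree is pruned to each
    alignment and foreground clades are marked from a branch-label file.
    Nested Goldman-Yang codon models (M0, two-ratios, M1a, M2a, model A and
    its null) are fitted by a built-in maximum-likelihood engine with
    Felsenstein pruning, and likelihood-ratio tests with optional Bonferroni
    correction classify candidate genes and positively selected codon sites.
    A codeml interoperability layer writes PAML control files and parses
    codeml main output so the scan can also drive the external program.
    Includes a codon-alignment simulator for all supported models and a
    neighbor-joining gene-tree monophyly check.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    parallel,
    ape,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
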