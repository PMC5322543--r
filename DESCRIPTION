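Package: mirdiverge
Title: Divergence of MicroRNA Binding Sites Between Duplicated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how plant microRNA (miRNA) binding sites are
    conserved or lost between paralogous genes after gene duplication.
    Provides a plant-style miRNA target scanner (weighted-mismatch duplex
    scoring with G:U wobble penalties and a k-of-n consensus over several
    scoring profiles), cataloguing of duplicate and singleton genes from
    all-vs-all protein similarity hits, classification of paralog pairs and
    triplets into same versus divergent binding-site patterns, young versus
    ancient miRNA age calls from cross-species homolog hit tables,
    expression-correlation and chi-square divergence statistics, a
    Nei-Gojobori (1986) Ka/Ks estimator with Jukes-Cantor correction,
    Fitch small-parsimony mapping of site presence/absence on gene-family
    trees, and a seeded synthetic-data generator with ground truth so the
    whole pipeline can be exercised end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    jsonlite
Config/testthat/edition: 3
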