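Package: barcodeRFLP
Title: COI Barcode PCR-RFLP Diagnostics and Phylogenetics for Pest Cockroaches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico pipeline for DNA-barcode based diagnosis of the five
    common pest cockroach species (Periplaneta americana, Blatta orientalis,
    Shelfordella lateralis, Blattella germanica, Supella longipalpa) from the
    mitochondrial COI barcode region. Implements virtual PCR with the Folmer
    primer pair, pairwise global alignment with DNA and amino-acid percent
    identity matrices, neighbor-joining phylogeny with outgroup rooting and
    monophyly tests, in-silico restriction digestion (AluI PCR-RFLP), an
    agarose-gel visibility model for single-enzyme diagnostic screening, and
    a seeded synthetic-panel generator that reproduces the published
    divergence structure and restriction maps for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
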