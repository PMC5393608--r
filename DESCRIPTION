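Package: BarcodeEval
Title: Tree- and Similarity-Based Evaluation of DNA Barcodes with
    Misidentification Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates the discriminatory power of DNA barcode loci and
    their combinations for species- and genus-level identification, the
    way plant-barcoding surveys do it: neighbour-joining trees with a
    bootstrap-supported monophyly criterion, and self-excluding best-hit
    searches against a local reference of all sequenced specimens.
    Includes multi-locus supermatrix concatenation with partition
    tracking, simple indel coding of shared alignment gaps, sequence
    recovery-rate accounting, a placement-audit workflow that flags
    specimens whose molecular placement contradicts their a priori
    taxonomic label, and a seeded simulator of multi-locus barcode
    datasets with a truth registry for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
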