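Package: plantNLR
Title: Evidence-Based Annotation and Classification of Plant NLR Immune Receptors
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts and annotates plant nucleotide-binding leucine-rich
    repeat (NLR) immune receptors from protein sequence sets using
    domain-signature evidence (InterProScan-format tables) and conserved
    NB-ARC sequence motifs. Provides an amino-acid position-weight-matrix
    scanner with exact p-values and Benjamini-Hochberg q-values, rule-based
    classification of proteins into NLR and NLR-related categories,
    compressed domain-architecture strings, NB-ARC domain extraction,
    greedy identity-threshold redundancy reduction with per-genus
    representatives, alignment column-coverage trimming, benchmarking
    metrics for annotation tools, and a synthetic-evidence generator for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Annotation, Classification, SequenceMatching, MotifAnnotation
RoxygenNote: 7.3.3
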