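Package: barcodeAudit
Title: Auditing DNA Barcode Reference Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing DNA barcode (COI) reference libraries:
    Kimura 2-parameter distances with pairwise deletion, neighbor-joining
    trees with deterministic tie-breaking, per-species barcode-gap
    statistics (maximum intraspecific and minimum interspecific
    divergence), single-linkage haplotype clustering at a divergence
    cutoff, fixed diagnostic-nucleotide discovery, rule-based specimen
    name assignment and provisional naming, misidentification screening,
    and a seeded simulator of multi-species barcode libraries with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ape,
    phytools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Phylogenetics, Classification, Clustering, SequenceMatching
RoxygenNote: 7.3.3
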