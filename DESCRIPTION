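Package: sanger16S
Title: Automated 16S rRNA Sanger Sequencing Identification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained pipeline for bacterial identification from
    partial 16S rRNA gene Sanger chromatograms. Reads and writes ABIF (.ab1)
    chromatogram files, quality-trims reads with a sliding-window profile or
    a stricter manual-review profile, calls mixed bases from trace data,
    merges bidirectional reads into consensus sequences, searches a local
    16S reference database with an affine-gap local aligner (or ingests
    BLAST tabular output), and applies a CLSI-style decision algorithm based
    on percent identity, query cover, aligned length, and distance to the
    next species to report species-level, genus-level, or inconclusive
    identifications. Includes a deterministic simulator of reference
    databases and forward/reverse Sanger read pairs for end-to-end testing
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
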