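Package: mcsp
Title: Metabarcoding by Capture Using a Single COI Probe
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational toolkit for single-probe hybridization-capture
    metabarcoding of COI barcodes. Provides a species-labelled reference
    database class built on Biostrings, in-silico amplicon extraction,
    probe equidistance evaluation via Jukes-Cantor distances, a
    strict-filter Smith-Waterman read assigner with naive
    lowest-common-ancestor taxonomy calls, maxSSS read-count presence
    thresholding, community relative-frequency estimation with rarefaction
    and enrichment metrics, read and mock-community simulators, and an
    end-to-end demultiplex/quality-filter/assign/quantify pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    BiocGenerics,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
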