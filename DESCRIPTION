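Package: gtrackr
Title: Type-Aware Genomic Track Model and the GTrack 1.0 Tabular Format
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a fifteen-type model of genomic annotation tracks
    built on four core informational properties (gaps, lengths, values,
    interconnections), together with full support for the GTrack 1.0
    tabular format: parsing, writing, validation, header expansion,
    subtype resolution, conversion to and from BED, bedGraph, WIG and
    GFF3, supporting tools (sort, standardize, complement columns), a
    binary columnar store with indexed random region access, and a
    deterministic generator of valid and deliberately corrupted fixture
    documents for all fifteen track types.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
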