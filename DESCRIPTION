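Package: bnsketch
Title: Boolean Network Sketches and Symbolic Candidate Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for specifying partial knowledge about asynchronous Boolean
    networks as sketches -- an influence graph, a partially specified Boolean
    network with uninterpreted update-function symbols, first-order properties
    of the update functions (essentiality, monotonicity, canalization), and
    dynamic properties written in hybrid CTL (HCTL) including constraints
    generated from binarized steady-state or time-series observations. A
    bit-parallel coloured model-checking engine computes, counts and
    enumerates every Boolean network consistent with a sketch, together with
    an explicit-state oracle for independent verification, generators for
    synthetic ground-truth sketches, and readers/writers for sketch JSON,
    BoolNet 'targets, factors' files and observation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
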