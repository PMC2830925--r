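Package: fpscreen
Title: Exact Tanimoto Threshold Screening of Binary Molecular Fingerprints
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exact similarity screening of databases of fixed-length binary
    molecular fingerprints: returns every record whose Tanimoto coefficient
    to a query fingerprint reaches a threshold. Implements a k-dimensional
    grid index keyed by per-fragment popcounts, Singlebit and Multibit tree
    bucket structures with provably sound pruning bounds, a staged
    popcount/XOR-folding baseline, and an instrumented linear scan, together
    with a seeded synthetic fingerprint generator and FPS-format input and
    output. All strategies are exact: pruning uses sound upper bounds only.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
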