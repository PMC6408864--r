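Package: bwtmerge
Title: Multi-String BWT, LCP and Document Array Construction by Merging, with
    Repeat, Overlap and de Bruijn Graph Applications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the multi-string Burrows-Wheeler transform, longest common
    prefix (LCP) array, document array and special-suffix bit array of a
    sequence collection by suffix-sorting sub-collections under a memory
    budget and merging the partial transforms with an iterative Gap-style
    procedure that emits LCP values to per-value pair files, later combined
    by a multiway merge. Single-scan application algorithms over the
    resulting arrays report Type 1 and Type 2 maximal repeats, all-pairs
    suffix-prefix overlaps above a length threshold, and the BOSS succinct
    representation of the order-k de Bruijn graph (optionally colored by
    sequence of origin). Brute-force reference implementations and seeded
    synthetic collection generators are included so every component is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
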