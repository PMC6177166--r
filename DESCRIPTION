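Package: blastvista
Title: Parse and Visualise BLAST Alignment Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parses the pairwise text and XML outputs of the NCBI BLAST+
    programs (BLASTp, BLASTn, BLASTx, tBLASTn, tBLASTx) into a validated
    alignment data model, recomputes high-scoring-pair statistics, and
    renders three visual components: a hit-distribution graphic (SVG),
    an HSP attribute table with CSV export, and a per-residue chunked
    alignment view, assembled into standalone HTML reports.  A seeded
    synthetic BLAST-output generator with retained ground truth serves
    as the oracle for the test suite, so no BLAST run is ever required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
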