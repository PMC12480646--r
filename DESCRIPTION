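Package: ednadetect
Title: Detection Thresholds and Decision Support for eDNA Metabarcoding Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calling species detections from multiplexed environmental
    DNA (eDNA) metabarcoding read tallies in the presence of sequencer index
    (barcode) swapping. Fits per-run cumulative-tail read-count cutoffs that
    separate probable swap artifacts (the long low-count tail) from low and
    positive detections, classifies every sample x primer x taxon tally,
    applies an invasive-species management decision framework (re-sampling,
    survey confirmation, escalation), and produces replicate-level and
    seasonal detection summaries. Includes a synthetic multiplexed-run
    simulator with planted occupancy and per-read index swapping for
    validating threshold sensitivity and specificity, and a simplified
    percent-identity rank assigner using optimized per-rank similarity
    cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
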