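Package: carenet
Title: Care-Team Collaboration Networks from EHR Activity Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs and compares multidisciplinary care-team
    collaboration networks from electronic health record (EHR) activity
    metadata, by shift type (day/night) and care location (emergency
    department, floor, paediatric intensive care unit). Implements the full
    chain: event-log preparation (timestamp normalisation, exclusions,
    location inference from admission/discharge/transfer data, functional-role
    resolution), natural-break segmentation of shifts via two-class Jenks
    optimisation on a 30-120 minute grid, the "working closely together"
    co-occurrence metric with per-shift weight normalisation, elbow-based edge
    thresholding on a LOWESS-smoothed rate-of-change curve, and overlapping
    link-community detection (weighted edge similarity, WPGMA/McQuitty edge
    clustering, partition-density cut). Includes a seeded synthetic EHR
    event-log generator with planted diurnal team structure so the whole
    pipeline is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
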