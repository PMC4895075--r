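Package: edf2csf
Title: Convert European Data Format Recordings to Cloudwave Signal Format
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads and writes European Data Format (EDF) electrophysiological
    recordings, parses clinical-annotation sidecar files with optional
    ontology-term mapping, partitions recordings into fixed-duration epochs,
    reorganizes sample-oriented data records into channel-oriented arrays with
    digital-to-physical calibration, and emits self-descriptive Cloudwave
    Signal Format (CSF) JSON documents with computed segment metadata. A
    synthetic-EDF generator with known ground truth makes the whole pipeline
    testable without patient data. Includes a command-line interface for
    directory-level conversion with file-level parallelism and per-file fault
    isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
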