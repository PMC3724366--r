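Package: nclistdb
Title: Nested Containment Lists with a Relational-Style Persistent Store for
    Genomic Interval Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds nested containment list (NCList) indexes over genomic
    intervals read from BED files, supports in-place insertion, deletion and
    coordinate updates of indexed intervals through an explicit case analysis
    over the node/edge/masterkey table representation, answers point and range
    overlap queries with instrumented operation counts, annotates sets of
    variant positions in batch, persists the index as relational-style tables,
    and benchmarks query scaling against naive-scan and start-sorted indexing
    strategies on synthetic interval databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
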