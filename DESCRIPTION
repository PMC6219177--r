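Package: svbench
Title: Benchmarking Toolkit for Somatic Structural-Variant Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for challenge-style benchmarking of somatic
    structural-variant (SV) callers: a read-level SV spike-in simulator
    with truth-set emission, two SV scoring schemes (region overlap and
    breakpoint closeness) with optimal one-to-one call/truth matching,
    ensemble call aggregation by majority vote, and error
    characterization of false-negative and false-positive breakpoints
    with univariate association tests and random forests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    clue,
    igraph,
    randomForest,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
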