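Package: framebench
Title: Reading-Frame-Aware Benchmarking of Metagenomic Gene Callers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates error-containing shotgun fragments from annotated
    prokaryotic genomes with exact ground truth, labels the true reading
    frame at each fragment's center, corrects predicted reading frames for
    cumulative insertion/deletion errors, and scores gene-caller output with
    a seven-label (six frames plus noncoding) confusion matrix yielding
    sensitivity, specificity, positive predictive value and overall accuracy
    with an explicit wrong-frame error class. Includes score-threshold ROC
    curves, per-position predicted coding-fraction profiles, parsers for
    common gene-caller output formats, and mock callers (a perfect-knowledge
    oracle and a parameterised noisy caller) so the whole evaluation stack is
    testable without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
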