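Package: ampligauge
Title: Evaluation of Short-Read 16S rRNA Amplicon Study Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A framework for comparing 16S rRNA gene short-read study
    designs. Excises in-silico amplicons for a primer window from a
    multiple sequence alignment, simulates single-end and fused paired-end
    reads, classifies them with a word-based naive Bayesian classifier
    reporting bootstrap confidence, measures precision by species-exclusion
    leave-k-out testing, calibrates rank-specific confidence thresholds for
    desired false-prediction rates via a conservative binomial procedure,
    computes taxonomy-gap-corrected classification coverage, and combines
    predictions from two gene regions. Includes a synthetic
    taxonomy/alignment generator so every stage can be exercised without
    reference database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
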