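Package: palacerel
Title: Room-Pattern Reliability and Memory Reinstatement Analysis for
    Memory-Palace fMRI Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the reliability of spatial-context
    ("room") neural patterns in searchlight surface data and for relating
    that reliability to reinstatement of room-paired objects during verbal
    recall. Implements searchlight construction by greedy redundancy
    removal, HRF-convolved design matrices and least-squares condition
    templates, the stability-minus-distinctiveness room reliability
    statistic, leave-one-participant-out multinomial decoding with
    contiguity-preserving permutation nulls and top-k network selection,
    reinstatement scoring from recall transcripts, Fisher-z composite
    reliability-reinstatement maps with label-shuffle permutation
    inference and FDR control, participant-specific model comparison, and
    a partial-correlation control for retrieval-time room reinstatement.
    Ships a synthetic-data generator that emulates the full study design
    (palace adjacency graph, randomized room-object pairings, video and
    recall runs, planted reliability and reinstatement effects) so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
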