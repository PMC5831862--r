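Package: mirmeta
Title: Small RNA Profiling, miRNA Family Evolution and Target Integration
    for Metamorphosis Studies
Version: 0.1.0
Authors@R:
    person("mirmeta", "developers", email = "mirmeta@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for small RNA sequencing studies of
    developmental transitions such as ascidian larval metamorphosis. Cleans
    raw small RNA reads (adapter location and trimming, poly-N, homopolymer
    and quality filters), classifies reads against annotation categories
    (rRNA, tRNA, snRNA, snoRNA, repeats, exons, introns, known miRNAs),
    clusters mature miRNAs into cross-species families under seed-anchored
    alignment constraints, reconstructs family gain and loss histories on a
    species tree under Dollo parsimony with taxon-level acquisition
    assignment, quantifies qPCR expression by the delta-delta Ct method
    normalized to a reference small RNA, integrates miRNA-target predictions
    from two predictors with expression anti-correlation, and performs
    hypergeometric over-representation analysis. A synthetic data generator
    with full ground truth makes every stage testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
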