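Package: oliveSRNA
Title: Small RNA Annotation, miRNA Homology and TAS3 Phasing Analysis for Olive
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a plant small-RNA (sRNA) annotation
    workflow built around 454-style sRNA libraries from juvenile and adult olive
    (Olea europaea) shoots: adapter stripping and artifact triage, size /
    complexity / non-coding-RNA filtering with exact per-filter accounting,
    size-class and 5' nucleotide composition profiling with reads-per-thousand
    normalization, homology classification of sRNAs against mature miRNA
    references with mismatch and overhang tolerance and variant typing,
    stem-loop precursor evaluation over a weighted base-pair-maximization
    folding backend, position-weighted miRNA target-site penalty scoring,
    RLM-5'RACE cleavage-site mapping in miRNA duplex coordinates, and
    miR390-anchored TAS3 tasiRNA phase-register analysis. A seeded synthetic
    read generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, Transcriptomics, Annotation
RoxygenNote: 7.3.3
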