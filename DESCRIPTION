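Package: svchromatin
Title: Structural Variant Mechanisms and Chromatin Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating structural-variant (SV) breakpoints of
    different mechanistic origin (NAHR, NHEJ, replication errors,
    retrotransposition, tandem repeats) to chromatin organization.
    Implements a circular-permutation null model with Z-score enrichment
    across genome segmentations, TAD boundaries and loop anchors;
    simulation of homology-constrained NAHR breakpoints by k-mer
    seed-and-extend homology search with length rejection sampling and
    compartment matching; peak and signal aggregation profiles around
    breakpoint anchors; Knight-Ruiz balancing and observed/expected
    normalization of Hi-C contact matrices with compartment- and
    distance-specific interaction comparison of breakpoint pairs;
    bin-level regression of NAHR density on DSB and homology predictors;
    and a closed-form estimator of the meiotic fraction of NAHR
    deletions. A synthetic-genome generator produces all inputs with
    planted ground truth so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
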