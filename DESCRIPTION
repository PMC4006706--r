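Package: urdomains
Title: Underrepresented-Domain Analysis for Polyploid Genomes from Binned Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls underrepresented (UR) domains in polyploid genomes (such as
    mouse trophoblast giant cells) from binned sequencing coverage of a
    polyploid sample against a matched diploid control. Provides normalized
    log2-ratio track construction, a run-based domain caller with a z-test
    significance model, per-domain percent-depletion statistics, cross-sample
    consensus and nestedness comparisons, TSS-distance-stratified permutation
    enrichment tests for genomic feature sets, two-state replication-timing
    segmentation with late-region containment analysis, discrimination of
    underreplication from somatic deletion via discordant paired-end spans,
    and a seeded synthetic-data generator with ground truth for end-to-end
    recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    yaml,
    optparse
Config/testthat/edition: 3
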