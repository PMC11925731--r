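Package: modcal
Title: Calibrated Detection and Differential Analysis of RNA Modifications
    from Nanopore Error Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for error-based RNA modification analysis from nanopore
    direct RNA sequencing of bacteria. Calibrates modification-calling
    thresholds (error of specific bases, odds ratio, adjusted p-value)
    against a catalogue of known modification sites via a precision/recall
    grid search with region-tolerant matching, merges called positions into
    signal regions, annotates regions by RNA biotype and metagene position,
    quantifies condition-dependent modification changes via delta-ESB with
    mass-spectrometry cross-validation, and classifies SELECT qPCR assays
    by the delta-delta-CT rule. Includes a ground-truthed synthetic data
    generator so the whole pipeline is testable without raw sequencing data.
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
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
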