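Package: psiscan
Title: Quantitative Pseudouridine Mapping from Bisulfite Deletion Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls pseudouridine (Psi) sites in bacterial RNA from paired
    bisulfite-treated and untreated per-base pileup counts, in which the
    bisulfite-Psi adduct causes reverse transcriptase to delete the modified
    base. Provides isolate-mode calling (depth, deletion-count and
    deletion-ratio filters with multi-sample high-confidence aggregation),
    community-mode calling for metatranscriptomes tolerant of
    strain-heterogeneity indels (fold-change plus Fisher's exact test,
    per-genome coverage gating, normalized site density, GC-group
    comparison and a strict 16S rule), sequence-motif preference testing
    against pseudouridine synthase (PUS) knockouts, transcript Psi-strength
    and PUS target assignment, ERCC spike-in normalized mRNA half-life
    estimation from rifampicin time courses, and simulators that generate
    pileups and decay count matrices with the statistical structure the
    pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
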