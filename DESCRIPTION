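Package: formalinQC
Title: Damage Profiling, Hard Trimming and Reference-Guided QC for
    Formalin-Fixed Specimen Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality control of short-read sequencing libraries built from
    formalin-fixed museum specimens and other heavily damaged historical
    DNA. Accumulates position-resolved base-misincorporation profiles (the
    12 reference-to-read substitution types as a function of distance from
    the 5' and 3' read ends), detects data-driven hard-trim lengths by a
    robust flatness criterion, applies read cleanup (hard trimming, exact
    duplicate removal, quality filtering, overlapping paired-end merging),
    and computes reference-based summaries: empirical error rates, binned
    coverage breadth and depth, pileup-based majority consensus with SNP
    counting and sequence dissimilarity, GC content and N50. A
    formalin-damage read simulator with truth alignments makes the whole
    pipeline testable without an external aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    IRanges,
    S4Vectors,
    jsonlite,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
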