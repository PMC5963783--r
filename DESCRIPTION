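Package: legoscreen
Title: Simulation and Deconvolution of Enzymatically Produced shRNA
    Suppressor Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-complexity shRNA screens built from subtracted
    transcriptomes. Implements an in-silico model of enzymatic shRNA library
    construction from AluI-digested cDNA (MmeI capture, loop-adapter ligation,
    Klenow extension, BpmI release), a second-order kinetic simulator of
    PCR-based suppression subtractive hybridization, a seeded synthetic
    pooled-screen generator (transcriptomes with planted suppressors,
    selection, error-bearing FASTQ reads), stem-loop-stem tag extraction and
    enrichment calling, tag-to-transcript mapping with redundancy clustering
    and minimal set-cover target identification, and the dual-library
    suppressor ranking that produces a scored hit table.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
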