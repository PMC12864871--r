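Package: shmgrammar
Title: Sequence-Context Analysis of Somatic Hypermutation at WRCH Motifs
Version: 0.1.0
Authors@R:
    person("shmgrammar", "maintainers", email = "shmgrammar@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the identity, local sequence context and
    position of WRCH motifs (W = A/T, R = A/G, H = A/C/T) shape somatic
    hypermutation of immunoglobulin V regions. Provides two-strand degenerate
    motif scanning with orientation classification, C-centred 15-mer context
    grouping and pyrimidine-dimer statistics over B-cell receptor repertoires,
    a native quantification pipeline for amplicon deep-sequencing mutation
    profiles (quality trimming, mate merging, gapless alignment, quality-aware
    pileups, normalized per-position frequencies and position-wise t-tests),
    a forward simulator of context-dependent cytosine deamination that
    generates germlines, mutated repertoires and paired-end reads, and
    trajectory descriptors (radius of gyration, RMSF and a per-nucleotide
    protein-surface distance) for interpreting deaminase-ssDNA binding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
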