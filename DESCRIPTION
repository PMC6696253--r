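Package: plastcompare
Title: Comparative Analysis of Chloroplast Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pairwise comparative analysis of annotated chloroplast
    (plastid) genomes: anchor-based whole-plastome alignment, sliding-window
    nucleotide diversity with divergence-hotspot calling, per-gene Kimura
    two-parameter distances and Nei-Gojobori (1986) Ka/Ks with selection
    classification, codon-level SNP calling and transition/transversion
    classification, codon usage and RSCU tabulation, quadripartite structure
    and inverted-repeat junction analysis, and MISA-style microsatellite
    (SSR) scanning with compound-SSR joining. Includes a synthetic plastome
    pair generator with a planted ground truth so every stage of the
    pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
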