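Package: cphotspot
Title: Discovery of Highly Variable Chloroplast Markers from Congeneric
    Genome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sliding-window scanning of aligned congeneric chloroplast
    genomes for mutational hotspots: per-window segregating sites and
    nucleotide diversity, threshold-based hotspot selection with
    annotation-derived locus names, cross-genus intersection of shared
    loci, universal primer design from conserved flanking sequence, and
    evaluation of locus resolution by exhaustive maximum parsimony and
    neighbor joining with bootstrap consensus. Includes a sequence
    evolution simulator (substitution hotspots, indels, microsatellites,
    small inversions) so the whole pipeline is testable without external
    genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
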