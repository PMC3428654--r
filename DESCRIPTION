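Package: ssrmine
Title: Mining and Marker Analysis of Simple Sequence Repeats in
    Transcript Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies simple sequence repeats (SSRs,
    microsatellites) in transcript sequences under explicit length
    thresholds: perfect tandem repeats of 1-6 bp units, imperfect
    (interrupted) repeats, and compound repeats, with canonical motif
    classes defined up to cyclic rotation and reverse complement.
    Summarises the resulting catalogue (unit-size, motif-class and
    copy-number distributions, repeat density, incidence), screens
    primer-pair candidates flanking each locus under GC-content,
    melting-temperature, primer-length and product-size constraints, and
    analyses marker polymorphism in germplasm panels: allele scoring,
    polymorphism information content (PIC), Jaccard band similarity and
    UPGMA dendrograms with Newick export.  Includes ground-truthed
    simulators for transcript sets with planted SSRs and for genotype
    band matrices with known allele frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
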