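Package: metaepi
Title: Metaepigenomic Motif Inference and Restriction-Modification Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers prokaryotic DNA methylation systems from single-molecule
    kinetic signals in metagenome-assembled genomes. Provides a degenerate
    IUPAC motif algebra (matching, reverse complement, subsumption, merging and
    novelty assessment against a restriction-enzyme reference), a seeded
    synthetic-community generator with planted sequence-specific methylation
    and strand-specific subread kinetics, a per-site modification caller
    producing Phred-scaled modification QVs, greedy degenerate-motif discovery
    with occurrence and methylation-fraction filters, per-contig methylation
    profiles as genome-binning support, and methyltransferase-motif congruence
    assignment over annotated restriction-modification genes. Ships reference
    tables of detected methylated motifs and RM-system genes from a freshwater
    lake microbial community survey.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
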