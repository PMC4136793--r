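Package: b3locus
Title: Annotation of a Basidiomycete B Mating-Type Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble and annotate the pheromone/receptor (B)
    mating-type locus of agaricomycete fungi from overlapping clone
    sequences. Includes six-frame small-ORF mining, CaaX-motif pheromone
    precursor classification with maturation-site prediction from the
    ER/TR cleavage consensus, hydropathy-based seven-transmembrane
    receptor topology and cytoplasmic-tail measurement, global alignment
    identity between receptor proteins, physical-map construction with
    in-silico PCR and GFF3/BED export, calibrated qRT-PCR relative
    expression with ANOVA/Tukey group tests, and a truth-labelled
    synthetic locus simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    multcomp,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
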