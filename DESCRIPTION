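Package: promacet
Title: Promoter Histone-Acetylation Dynamics from Spike-In ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for stranded single-end ChIP-seq of
    promoter histone acetylation (H3K9ac), histone H3, RNA polymerase II
    (Rpb1) and transcription-factor occupancy in budding yeast, with a
    fixed-proportion S. pombe spike-in. Reads are transformed with a
    strand shift-and-extend step into fragment-midpoint coverage,
    quantified over promoter, +1-nucleosome and gene-body windows,
    normalized by spike-in or library size with an optional mock-IP
    ratio, and contrasted between treated and vehicle conditions as
    log2 fold changes. Downstream analyses include a dual-threshold
    stress-repressed gene-set classification, gene-group statistics
    (Mann-Whitney, one-way ANOVA with Dunnett contrasts, Pearson),
    promoter motif enrichment for the PAC and RRPE elements, and
    +1-nucleosome-anchored metagene profiles and sorted heat-map
    matrices. A synthetic-data generator with planted ground truth
    makes every stage testable without deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    multcomp,
    stats,
    utils,
    withr,
    yaml
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
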