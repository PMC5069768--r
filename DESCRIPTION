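Package: panlink
Title: Linking Pan-Genomes and Pan-Metabolomes of Bacterial Strain Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated mining of comparative genomic and untargeted
    metabolomic data for closely related bacterial strains. Computes pan- and
    core-accumulation curves for gene families and molecular features, builds
    gene families by the 50/50 identity-coverage rule, derives per-gene
    presence/absence barcodes from bidirectional best hits, groups predicted
    biosynthetic pathways into operational biosynthetic units, matches
    chemotype presence patterns against gene barcodes to propose candidate
    biosynthetic gene clusters, screens for halogenated metabolites by linear
    mass-defect windows and isotope-pattern simulation, builds MS/MS molecular
    networks with a modified cosine score, and selects discriminative features
    with a genetic-algorithm-wrapped linear support vector machine. Ships a
    seeded synthetic-data generator that plants recoverable ground truth so
    the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
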