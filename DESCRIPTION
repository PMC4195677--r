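Package: gstcurate
Title: Template-Guided Curation of Ortholog Gene Models in Multi-Species
    Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to re-annotate orthologous gene models in a target genome
    against a curated reference (template) species, as done for the insect
    glutathione transferase (GST) superfamily across the twelve sequenced
    Drosophila genomes. Covers start-site rescue, exon/intron reassignment,
    sequencing-gap (N-run) detection, codon-aware frameshift-indel detection
    with virtual single-nucleotide edits, pseudogene calling against catalytic
    anchors, projection of alternative-splicing isoform structures onto
    orthologous loci, signed-permutation micro-synteny analysis (breakpoints,
    inversions, transpositions), and Jukes-Cantor/neighbor-joining distance
    trees of the curated proteins. A deterministic synthetic-genome generator
    with a ground-truth defect ledger makes the whole pipeline testable
    end-to-end without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
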