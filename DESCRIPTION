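Package: sagdiv
Title: Phylogenetic-Diversity-Guided Selection and QC of Single-Cell
    Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for microbial single-cell genomics
    surveys: assembly quality metrics and tetranucleotide-frequency PCA
    contamination screening, amplification-kinetics cost estimation from
    real-time whole-genome-amplification curves, budget- and
    cardinality-constrained cell selection maximizing Faith's phylogenetic
    diversity (the Noah's Ark problem) with exact, brute-force and greedy
    solvers, per-clade phylogenetic gain after placement of new genomes on
    a reference tree, gene-catalog novelty labeling by percent nucleotide
    identity with permutation-based annotation-category enrichment, and a
    Wilcoxon/Benjamini-Hochberg comparison layer. Ships a synthetic-data
    generator with controlled ground truth so the whole workflow is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
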