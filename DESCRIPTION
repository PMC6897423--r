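Package: neoYtools
Title: Neo-Sex Chromosome Genotyping, Haplotype Dating, and Degeneration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing young neo-Y chromosomes from paired
    male/female resequencing data. Infers haploid neo-Y genotypes from
    diploid variant calls, computes windowed diversity and differentiation
    statistics (pi, Fst, Dxy, Da), builds and classifies per-window
    phylogenies to paint neo-Y haplotype blocks and date the cessation of
    male recombination from branch-length ratios, quantifies allele-specific
    expression with DNA-based reference-bias correction, annotates coding
    degeneration (synonymous/nonsynonymous/nonsense substitutions,
    frameshifts, Ka/Ks by NG86), and tests tissue-bias enrichment by
    permutation. Includes a synthetic-cohort generator so every stage of the
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
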