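Package: atgenome
Title: Base-Composition Genome Phenotypes and UV-Signature Mutation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse genome divergence between wild and domesticated
    plant populations through base composition across polymorphic sites. The
    per-accession fraction of SNP alleles that are A or T ([AT]) is treated as
    a genome phenotype and summarised overall, by substitution type, in
    sliding windows, and within genomic strata (genic/non-genic,
    pericentromere, transposable elements, selective sweeps, CG-methylated
    windows). Trinucleotide motif enrichment around SNPs is tested against an
    empirical resampled null, population-private variants are polarized with
    an outgroup and typed into 96 strand-collapsed mutation classes for
    between-population spectrum comparison, and UV-damage-repair gene
    enrichment near trait-associated SNPs is tested with a proportion test.
    A parameterized synthetic-study generator with planted ground truth
    supports calibration and power analysis of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
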