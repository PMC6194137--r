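Package: haplopop
Title: Haploid-Aware Population Genomics and Mixed-Model Association
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative population genomics for haplodiploid species in
    which males are haploid, built around a socially polymorphic halictid
    bee study design (three eusocial and three solitary populations of
    haploid males plus two outgroup haplotypes). Provides a synthetic
    haplodiploid genotype simulator (Balding-Nichols population structure,
    block-wise linkage disequilibrium, heterozygous-artifact and missing
    calls, planted behavior-associated variants), a post-calling variant
    and individual QC cascade, diversity and Weir-Cockerham differentiation
    statistics with a label-permutation null, LD decay and variance
    inflation factor pruning, genotype principal components, a univariate
    linear mixed model association scan with a centered genomic relatedness
    matrix and Benjamini-Hochberg FDR, strand-aware regulatory and coding
    SNP annotation with hypergeometric enrichment tests, and the downstream
    qPCR delta-CT and reporter-assay ANOVA/Tukey statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
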