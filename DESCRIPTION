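Package: irQTL
Title: Isoform-Ratio QTL Mapping, Heritability Enrichment and Mendelian
    Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps cis quantitative trait loci for isoform usage ratios
    (irQTL): variants that shift the relative proportions of a gene's
    isoforms while leaving total gene expression unchanged. Provides
    isoform-ratio phenotype construction with quality control, genomic
    kinship and principal components, rank-based inverse normal
    transformation, a vectorized closed-form linear-regression cis scan
    with locus and lead-variant calling, cross-filtering against
    gene-level eQTL, stratified LD score regression for heritability
    enrichment of irQTL annotations with block-jackknife errors, and
    two-sample Mendelian randomization (inverse-variance weighted and
    Egger) of isoform ratios on complex traits. A synthetic-data module
    generates LD-structured genotypes, genetically regulated isoform
    proportions with opposite-sign effects that cancel at the gene
    level, and outcome-trait GWAS summary statistics with configurable
    heritability enrichment and causal effects, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    yaml,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'irQTL-package.R'
    'irqtl.R'
    'ldsc.R'
    'mr.R'
    'phenotypes.R'
    'pipeline.R'
    'popstruct.R'
    'scan.R'
    'simulate.R'
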