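Package: cisMetaQTL
Title: Multi-Cohort cis-eQTL Mapping, GWAS Meta-Analysis, and Regulatory
    Variant Prioritization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for prioritizing candidate functional
    variant-gene pairs from germline genetic and transcriptomic data.
    Provides covariate-adjusted cis-eQTL mapping within a window around
    gene transcription start sites, fixed-effects inverse-variance
    meta-analysis across cohorts with Cochran's Q and I-squared
    heterogeneity triage, annotation enrichment of lead eQTLs against
    MAF- and TSS-distance-matched non-eQTL controls, case-control GWAS
    association under an additive model with genomic-inflation
    diagnostics and analytic trend-test power, and threshold-based
    intersection of GWAS and eQTL evidence. A synthetic-cohort module
    generates LD-blocked genotypes in Hardy-Weinberg proportions,
    expression with additive cis effects and hidden confounding factors,
    and liability-model case-control phenotypes, with full ground truth
    for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, SNP, GenomeWideAssociation,
    GeneRegulation, StatisticalMethod
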