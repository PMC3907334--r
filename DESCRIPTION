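Package: riskenhancer
Title: Functional Annotation of GWAS Risk Loci in Regulatory Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-GWAS functional-annotation toolkit for regulatory
    genomics. Finds proxy SNPs in linkage disequilibrium with GWAS index
    SNPs from phased haplotype panels, intersects them with chromatin
    biofeature tracks (DNase I hypersensitivity, histone-mark and
    transcription-factor ChIP-seq peaks) and classifies them by putative
    functional category; scores allele-specific disruption of
    transcription-factor response elements with positionally weighted
    position-weight-matrix (PWM) matching; tests per-factor disruption
    counts against bootstrap-resampled SNP backgrounds with
    Bonferroni-corrected empirical intervals; and fits a hierarchical
    Bayesian model of allele-specific enhancer activity in luciferase
    reporter assays with plasmid-prep, transfection and plate-batch
    effects.  Ships a synthetic-data generator with known ground truth
    (block-LD haplotype panels, biofeature tracks, PWM libraries with
    planted allele-disrupting variants, plate-structured reporter data)
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
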