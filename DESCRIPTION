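Package: cnvqtl
Title: Dissection of a Multi-Allelic Copy-Number QTL with Pedigrees,
    Haplotypes and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect a quantitative trait locus driven by a
    multi-allelic tandem copy-number variant (CNV), modelled on the
    bovine chromosome 6 clinical-mastitis-resistance locus. Provides a
    seeded synthetic cohort generator (pedigree, haploid CNV alleles,
    read depths, phased haplotype panel with a selective sweep,
    allele-depth read counts, polygenic trait, negative-binomial
    expression); depth-based diploid copy-number calling with
    pedigree-constrained haploid allele resolution and Mendelian
    checking; allelic-imbalance genotype correction and tag-SNP
    discovery; genomic-relationship linear mixed-model association with
    conditional scans; extended haplotype homozygosity (EHH) and
    integrated haplotype score (iHS) selection scans; cis-eQTL mapping
    with median-of-ratios normalization and hidden-factor
    residualization; and SMR/HEIDI causal-gene prioritization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
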