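# cnvqtl

Dissection of a quantitative trait locus driven by a multi-allelic tandem
copy-number variant (CNV), modelled on the clinical-mastitis-resistance
locus on bovine chromosome 6 in Holstein-Friesian cattle.

## The problem

A GWAS peak for an economically important disease trait sits on top of a
~12 kb tandemly multiplicated segment overlapping the 3' end of the *GC*
gene. The locus is multi-allelic: one chromosome can carry 1 copy
(wildtype, *Wt*) or 4–6 copies (multiplicated, *Mul*) of the segment.
Standard SNP pipelines handle such a locus badly — variant callers miscall
heterozygotes inside the duplication because reads from the multi-copy
haplotype swamp the wildtype allele, and array-based fine mapping never
sees the CNV at all. `cnvqtl` implements the full chain of evidence needed
to pin such a locus down:

1. **Multi-allelic CNV genotyping from read depth.** The diploid copy
   number is `round(2 × FC)`, where `FC` is the mean read depth of the CNV
   interval over a copy-neutral flank. Each diploid CN is decomposed into
   haploid allele pairs over the allele set `{1, 4, 5, 6}` (a diploid CN of
   10 may be 4+6 or 5+5), and the ambiguity is resolved through the
   pedigree by constraint propagation plus exhaustive enumeration within
   family components, with full Mendelian-consistency reporting.
2. **Allelic imbalance.** At a heterozygous site inside the CNV the
   expected alternative-read fraction is not 1/2 but `c/(c + 1)` for a
   *Wt/Mul* carrier with `c` copies; genotypes are re-evaluated by binomial
   likelihood and miscalls (Ref/Alt called as Alt/Alt) are corrected.
   Tag SNPs — sites whose dosage is in near-perfect LD (r² ≥ 0.98) with
   the biallelically coded CNV — are discovered and ranked.
3. **Mixed-model association.** The trait model is `y = 1μ + Xb + g + e`
   with polygenic effect `g ~ N(0, σ²_g G)` for a VanRaden genomic
   relationship matrix `G`; variance components are estimated once by
   REML (eigendecomposition + one-dimensional profile optimization) and
   reused across variants (EMMAX-style GLS), with conditional scans on
   lead variants and a chromosome-wide Bonferroni threshold
   `-log10(α/n)`.
4. **Selection scanning.** Extended haplotype homozygosity (EHH) and the
   integrated haplotype score `iHS = ln(iHH_A / iHH_D)`, standardized
   within derived-allele-frequency bins, detect the recent positive sweep
   that carried the Mul haplotype to high frequency.
5. **cis-eQTL mapping and causal-gene prioritization.** Median-of-ratios
   normalization, PC outlier screening (top 4 PCs, 3.5 sd), hidden-factor
   residualization, per-variant regression within ±1 Mb of the focal gene,
   and summary-data Mendelian randomization:
   `T_SMR = z²_G z²_E / (z²_G + z²_E)` against χ²(1) with the HEIDI
   heterogeneity test (χ²(m−1) on per-SNP `b_xy` differences under the
   LD-derived covariance). A gene is prioritized iff `-log10 p_SMR > 5`
   and `p_HEIDI > 0.05`.

All stages are exercised end-to-end on a seeded synthetic cohort generator
that emulates the study design: 266 animals of which 240 form 80 trios,
haploid CN alleles {1, 4, 5, 6} at frequencies 0.39/0.54/0.03/0.05, 26X
Poisson sequencing depth, five intra-CNV tag SNPs, a sweep haplotype
carrying the Mul alleles, a polygenic trait with a Mul-dosage effect, and
negative-binomial expression with canonical (~98%) and alternative (~2%)
transcripts of the focal gene.

## Worked example

```r
library(cnvqtl)

cfg <- sim_config(n_individuals = 150, n_trios = 40, n_snps = 500, seed = 8)
manifest <- run_pipeline(cfg, "demo_run")
cat(readLines("demo_run/report.txt"), sep = "\n")
```

```
cnvqtl pipeline report
======================
CN genotyping: 148/150 resolved; Mendelian incompatibilities: 0
Tag SNPs at r2 >= 0.98 in CNV: 5
Association lead: v237 at -log10p = 3.06 (threshold 4.48)
iHS peak |std| = 4.19 at 91,065,695
SMR prioritized gene(s): none
Trait/GC-eQTL p-value correlation rho = 0.61
```

Reading the report: all but two animals got a fully resolved haploid CN
pair (the rest stay flagged, never guessed), with zero Mendelian
conflicts; the five designed intra-CNV tag SNPs are recovered at
r² ≥ 0.98; at this demonstration size (n = 150) the trait lead variant
does not clear the Bonferroni line and SMR stays below its significance
threshold — power analyses in the test suite use the larger split-cohort
design (600 GWAS / 175 expression samples), where the focal gene is
prioritized and its HEIDI test passes; the trait and expression p-value
profiles correlate at ρ = 0.61 over the shared cis window.

Individual stages are plain functions returning data frames or small S3
objects (`print()` methods included): `simulate_cohort()`,
`call_diploid_cn()`, `resolve_pedigree_cn()`, `check_mendelian()`,
`correct_imbalanced_genotypes()`, `find_tag_snps()`, `compute_grm()`,
`fit_null_lmm()`, `mixed_model_scan()`, `bonferroni_threshold()`,
`compute_ehh()`, `ihs_scan()`, `standardize_ihs()`, `normalize_counts()`,
`cis_eqtl_scan()`, `smr_heidi()`, `coloc_correlation()`, plus VCF/FAM/BED
readers and writers.

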