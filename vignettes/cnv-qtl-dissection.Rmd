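---
title: "Dissecting a multi-allelic CNV QTL: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a multi-allelic CNV QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvqtl)
```

# Scope

`cnvqtl` implements the analysis chain for a quantitative-trait locus
driven by a multi-allelic tandem copy-number variant: depth-based CNV
genotyping with pedigree resolution, allelic-imbalance-aware genotype
correction and tag-SNP discovery, mixed-model association with
conditional scans, EHH/iHS selection scanning, cis-eQTL mapping, and
SMR/HEIDI causal-gene prioritization. Because the original animal data
cannot ship with a package, every stage is validated against a seeded
synthetic cohort generator whose defaults reproduce the study design:
a 266-animal Holstein-Friesian cohort with 80 parent-offspring trios,
haploid copy-number alleles {1, 4, 5, 6} at frequencies
0.39/0.54/0.03/0.05 (renormalized from their printed two-decimal
rounding, which sums to 1.01), 26X sequencing depth, a ~12 kb CNV at
positions 88,681,767–88,693,545 of a 10-Mb window, and five intra-CNV
tag SNPs.

# Copy-number genotyping

## Depth model and diploid calls

Read depth is modelled per `depth_bin_bp` (100 bp) bin as Poisson with
mean `mean_coverage × copies / 2`, averaged over the CNV interval and
over a `flank_width` (20 kb) copy-neutral flank. An optional
negative-binomial overdispersion multiplier exists but defaults off: the
study reports only mean coverage, and at 26X averaged over ~12 kb the
Poisson mean is already essentially deterministic. The diploid copy
number is `round(2 × FC)` with ties away from zero — a deliberate hard
rounding that matches reading integer peaks off a fold-change histogram
and keeps calls deterministic; mixture-model refinements are out of
scope. On the default simulation ≥ 99% of diploid calls equal the truth.

## Haploid resolution through the pedigree

Each diploid CN is decomposed over the allele set `A = {1, 4, 5, 6}`
(an input, not rediscovered from data): a diploid CN of 10 is `{(4,6),
(5,5)}`, of 2 is `{(1,1)}`, of 3 is empty. Candidate sets shrink by
constraint propagation to a fixpoint — a child's pair must be formable
from one allele of each genotyped parent and a parent's pair must be
able to supply all its children — followed by exhaustive joint
enumeration within family components of at most `max_component` (10)
members, which finalizes exactly the assignments a brute-force search
over all candidate combinations would keep (the test suite asserts this
equivalence on an exhaustive trio grid and on random multi-child
families). Individuals whose candidate set stays larger than one are
reported unresolved, never imputed. One logical refinement of the
"relatives resolve CN10" rule emerged during implementation: a resolved
parent forces a CN10 child to (4,6) exactly when that parent carries no
5-allele; a (4,5) parent leaves (5,5) possible. Mendelian verdicts are
judged against the depth-implied candidate sets, so an impossible trio
reads "incompatible" rather than silently vanishing during propagation.

## Allelic imbalance

For a *Wt/Mul* heterozygote with Mul copy number `c`, the expected
alternative-read fraction at an intra-CNV site whose alternative allele
rides the Mul haplotype is `c/(c+1)` (0.8 for CN4, 6/7 for CN6), not
1/2 — precisely why naive callers emit Alt/Alt miscalls there. The
corrector re-evaluates every intra-CNV call by binomial likelihood over
the genotype hypotheses implied by the resolved CN pair, with a
sequencing-error rate `eps = 0.01` (the study states none; 1% is a
conventional Illumina figure) for the homozygous hypotheses. Corrections
that would create a new site-level trio Mendelian error are reverted, so
the corrector can only reduce the trio error count.

# Association model

The trait model is `y = 1μ + Xb + g + e`, `g ~ N(0, σ²_g G)`,
`e ~ N(0, σ²_e I)` (equal residual variances). `G` is the VanRaden
cross-product GRM from centred, frequency-scaled dosages, with an option
to exclude a window (e.g. the QTL region) from the markers so the causal
signal is not absorbed into the polygenic term. REML maximizes the
profiled criterion over `log10(σ²_g/σ²_e) ∈ [−10, 10]` (tolerance 1e-6)
after a single eigendecomposition, comparing against the `σ²_g = 0`
boundary. The per-variant scan holds the variance components fixed
(EMMAX-style) and performs weighted least squares in the rotated space
with a per-variant residual-scale t-test, which reduces *exactly* to OLS
when `σ²_g = 0`; an exact per-variant REML refit is available behind
`exact = TRUE`. Conditioning SNPs enter as fixed covariates; a variant
collinear with the covariates (including itself) is flagged untested
with an undefined p-value. The CNV enters association biallelically as
the Mul-allele count. Type-I error at nominal 0.05 is calibrated within
[0.04, 0.06] on a 10,000-variant null at n = 500 in the test suite.

One caveat the tests document: estimating variance components with a GRM
built from a *single 10-Mb region* against a trait whose polygenic part
follows the dense pedigree relationship recovers little heritability —
the regional GRM is a noisy, low-rank proxy. Parameter-recovery tests
therefore use genome-wide-like independent markers; the pipeline's
regional fit is still a valid working correction for the scan.

The colocalization measure is Spearman's rank correlation between the
two `-log10 p` profiles on shared variants (the study does not name its
estimator; Pearson is available as an option).

# Selection scan

EHH at position `x` for a core allele is
`Σ_h C(n_h, 2) / C(n_c, 2)` over groups of carrier haplotypes still
identical from the core to `x`, computed left and right independently;
it is 1 at the core and non-increasing outward. iHH integrates each
curve over physical distance by the trapezoid rule, truncated with
linear interpolation where EHH crosses 0.05 (the conventional cutoff;
the study defers to its scan tool's defaults). `iHS_u = ln(iHH_A/iHH_D)`
is negative at a sweep on the derived allele, standardized within 20
equal-width derived-allele-frequency bins, and referred to a two-sided
standard normal (the p-value convention is not printed in the source
study; the normal reference is documented here as the package's choice).
Ancestral alleles come from the panel annotation — simulated truth — not
outgroup inference.

A structural point worth stating: sites *inside* a swept segment
condition on their own position being covered and therefore carry
systematically longer shared haplotypes — larger iHH — than the selected
site itself. The maximum |iHS| of a scan is consequently expected *near*
rather than *at* the swept core (in the motivating study the iHS lead
SNP sits ~200 kb from the CNV). The sweep-recovery property tested here
is therefore regional: the scan maximum must localize to the swept
neighbourhood (within 2.5 Mb of the CNV) with the correct sign at the
core, which holds in every seeded replicate at the defaults.

# Expression and causal-gene prioritization

Counts are normalized by median-of-ratios size factors (genes with a
zero count anywhere are excluded from factor estimation; factors are
rescaled to geometric mean 1, a convention that leaves between-sample
ratios untouched — the scale-equivariance the tests assert).
Sample QC removes outliers beyond 3.5 sd on any of the top 4 expression
PCs, one pass only. Hidden confounders are removed by regressing each
gene on the top K = 10 expression PCs — a deterministic surrogate for
Bayesian factor models (PEER in the study), chosen to keep the stage
dependency-free; the focal cis region's genes can be excluded from
factor estimation so a strong cis effect cannot leak into the factors,
and the generator includes 150 genome-background genes so the factor
substrate is realistic. cis-eQTL mapping is per-variant linear
regression within ±1 Mb of the feature, gene- and transcript-level
phenotypes handled identically.

SMR uses the top cis-eQTL variant (eQTL p below 5e-8) as instrument:
`b_xy = b_GWAS / b_eQTL`, `T_SMR = z²_G z²_E/(z²_G + z²_E)` on χ²(1).
HEIDI tests heterogeneity of `b_xy` across up to 20 secondary cis-SNPs
(eQTL p < 1.57e-3, LD r² to the instrument within [0.05, 0.9]) using the
delta-method covariance of the `b_xy` estimates under the signed LD
matrix, `T = d'V⁻¹d` on χ²(m−1) (pseudo-inverse fallback if `V` is
singular). A gene is prioritized iff `-log10 p_SMR > 5` and
`p_HEIDI > 0.05`; a gene with no valid instrument is untestable, never
prioritized. The power property uses a split-cohort design mirroring the
study's asymmetry — 600 GWAS samples, 175 expression samples — since the
instrument needs GWAS power that 175 animals cannot provide.

# The synthetic cohort: what it emulates and what it does not

The generator is a structural emulator, not a population-genetic
simulator. Design and defaults:

* **Pedigree**: 80 trios (two founder parents each) plus unrelated
  founders to 266 animals. Founders draw CN alleles i.i.d. from the
  configured frequencies; children inherit one allele per parent,
  uniformly — Mendelian by construction.
* **Haplotypes**: a pool of 20 ancestral haplotypes generated
  genealogically (each derives from a random earlier one with per-site
  divergence 0.05), over 2,000 sites spanning 10 Mb (5-kb spacing) at
  background frequencies Uniform(0.2, 0.8). Wildtype founder haplotypes
  are mosaics over the pool with exponential segment lengths (mean
  50 kb); every Mul haplotype copies a single sweep founder haplotype
  across the CNV and an Exponential(1 Mb) distance beyond each boundary.
  The related-pool construction matters: with mutually independent pool
  haplotypes, EHH collapses at the first flanking site and iHS becomes
  sparse-site identity-by-state noise. Transmission to children applies
  crossovers at 1e-8 per bp, phase-consistent with the inherited CN
  allele. Tag sites carry the alternative allele on every Mul haplotype
  and the reference on every Wt haplotype — the r² = 1 tagging the
  analysis exploits.
* **Trait**: `y = μ + β·MulDosage + g + e` with `β = 0.5` residual-sd
  units, `h² = 0.30`, `g` drawn from the pedigree numerator relationship
  matrix. De-regressed breeding values are emulated only as equal
  residual variances; daughter contributions are not modelled.
* **Expression**: negative-binomial counts (dispersion 0.1), lognormal
  library sizes (sd 0.2), focal-gene log-mean increasing 0.10 per copy
  above the diploid baseline, canonical/alternative transcripts at
  98%/2%, 12 cis neighbour genes and 150 background genes without CN
  effects.
* **Seeding**: one master seed expands into per-stage substreams
  (hash of the stage name), so any stage can be regenerated
  independently and whole cohorts are byte-identical under a seed.

Not emulated: read-level data (depths and allele counts are generated
directly), genetic-map distances (physical only), coalescent population
history, genotyping-array error modes, and multi-breed structure.
Passing tests on this generator demonstrate the *algorithms* — not that
real cattle data meet the generator's assumptions; in particular the
clean separation of depth peaks at 26X and the exact tag-SNP linkage are
idealizations that real data only approximate.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-variance markers are
excluded from the GRM (all-monomorphic input errors), zero-variance
sites are skipped with a warning in tag discovery, singleton core
alleles make EHH undefined (error), zero-variance frequency bins flag
their sites unstandardizable, monomorphic variants are flagged untested
in scans, and a missing CN genotype leaves a site's calls unchanged with
a warning. The REML optimizer is `optimize()` on the log variance ratio
(unimodal in practice; the boundary fit is always compared). Atomic
file writes (temp-then-rename) guarantee a crashed run never leaves a
half-written table.

Test problem sizes are chosen for single-CPU minutes: cohorts of 60–300
for unit tests; 266 (the study size) for frequency recovery; 250
animals / 500 haplotypes and 10 seeded replicates for sweep recovery;
n = 500 with 10,000 variants for association calibration; 775 split
600-GWAS / 175-expression for SMR power, 10 replicates. The magnitudes
of the motivating datasets (thousands of progeny-tested bulls,
whole-chromosome variant sets) are deliberately out of desk scale;
properties that depend on them are covered by these scaled analogues.

# Limitations

* The resolver is a simplified trio-transmission engine; probabilistic
  linkage-phasing evidence (used in the original study) is out of scope,
  so resolution relies on depth calls and pedigree constraints alone.
* iHS standardization over a 10-Mb window is noisier than genome-wide
  standardization; the swept fraction of the window inflates bin
  variances, which is why the regional localization property (not a
  per-site percentile) is the tested guarantee.
* The EMMAX single-fit approximation slightly misstates per-variant
  variance components when a variant explains much variance; the exact
  refit flag exists for such cases.
* HEIDI's delta-method covariance assumes independent GWAS and eQTL
  cohorts (true of the emulated design) and moderately sized effects.
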