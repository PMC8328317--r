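#' Simulation configuration for a synthetic CNV cohort
#'
#' Builds and validates the configuration object consumed by all
#' `simulate_*()` generators. Defaults reproduce the structure of the study
#' population the package models: a Holstein-Friesian cohort of 266 animals
#' of which 240 form 80 parent-offspring trios, a tandem CNV on a 10-Mb
#' chromosome window with haploid copy-number alleles {1, 4, 5, 6} at
#' frequencies 0.39/0.54/0.03/0.05, ~26X sequencing depth, five intra-CNV
#' tag SNPs, a recent positive sweep carrying the multiplicated (Mul)
#' alleles, a polygenic quantitative trait with a Mul-dosage effect, and
#' negative-binomial expression of a focal gene with canonical (98%) and
#' alternative (2%) transcripts.
#'
#' @param n_individuals total cohort size (founders created as needed so
#'   that every trio has two parents).
#' @param n_trios number of parent-offspring trios.
#' @param cn_allele_freqs named numeric vector mapping haploid copy number
#'   to population frequency; must sum to 1.
#' @param mean_coverage mean sequencing depth (reads) of the diploid genome.
#' @param n_snps total number of biallelic sites in the haplotype panel
#'   (including `n_tag_snps` intra-CNV tag sites).
#' @param n_tag_snps number of intra-CNV sites carrying the alternative
#'   allele on every Mul haplotype.
#' @param region_start,region_span 1-based start (bp) and span (bp) of the
#'   simulated chromosome window.
#' @param cnv_interval length-2 integer, 1-based inclusive CNV boundaries.
#' @param sweep_mean_length mean one-sided length (bp) of the segment each
#'   Mul haplotype shares with the common sweep founder haplotype
#'   (exponentially distributed per side).
#' @param neutral_mean_length mean mosaic segment length (bp) for neutral
#'   (wildtype) haplotypes copying from the founder haplotype pool.
#' @param n_founder_haps size of the ancestral founder-haplotype pool.
#' @param pool_divergence per-site divergence probability between an
#'   ancestral pool haplotype and the haplotype it derives from;
#'   controls how fast extended haplotype homozygosity decays between
#'   distinct ancestral lineages.
#' @param recomb_rate per-bp recombination probability per meiosis.
#' @param beta_mul additive trait effect per Mul allele (residual-sd units).
#' @param h2 narrow-sense heritability of the polygenic background.
#' @param expr_base_mean baseline expected count of the focal gene.
#' @param expr_log_fc log-scale expression increase per extra copy of the
#'   CNV segment (total copies above the diploid baseline of 2).
#' @param expr_dispersion negative-binomial dispersion (1/size).
#' @param transcript_shares length-2 numeric, canonical/alternative
#'   transcript baseline shares; must sum to 1.
#' @param n_null_genes number of neighbouring genes with no CN effect.
#' @param n_background_genes number of genome-background genes (outside
#'   the cis window, no CN effect) included so hidden-factor estimation
#'   has a realistic genome-wide substrate.
#' @param libsize_sd lognormal sd of per-sample library-size factors.
#' @param depth_bin_bp width (bp) of the depth-counting bins used when
#'   averaging read depth over a region.
#' @param flank_width width (bp) of the copy-neutral flank used as the
#'   depth denominator.
#' @param overdispersion optional depth overdispersion multiplier
#'   (negative-binomial); `NULL` (default) keeps pure Poisson depth.
#' @param seed integer master seed; expanded into per-stage substreams so
#'   stages can be rerun independently.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 30, n_trios = 8, n_snps = 60, seed = 1)
#' cfg$cn_allele_freqs
#' @export
sim_config <- function(n_individuals = 266,
                       n_trios = 80,
                       cn_allele_freqs = c("1" = 0.39, "4" = 0.54,
                                           "5" = 0.03, "6" = 0.05),
                       mean_coverage = 26,
                       n_snps = 2000,
                       n_tag_snps = 5,
                       region_start = 84e6,
                       region_span = 10e6,
                       cnv_interval = c(88681767L, 88693545L),
                       sweep_mean_length = 1e6,
                       neutral_mean_length = 5e4,
                       n_founder_haps = 20,
                       pool_divergence = 0.05,
                       recomb_rate = 1e-8,
                       beta_mul = 0.5,
                       h2 = 0.30,
                       expr_base_mean = 2000,
                       expr_log_fc = 0.10,
                       expr_dispersion = 0.1,
                       transcript_shares = c(canonical = 0.98,
                                             alternative = 0.02),
                       n_null_genes = 12,
                       n_background_genes = 150,
                       libsize_sd = 0.2,
                       depth_bin_bp = 100,
                       flank_width = 20000,
                       overdispersion = NULL,
                       seed = 1L) {
  if (n_individuals <= 0 || n_trios < 0)
    stop("n_individuals must be positive and n_trios non-negative")
  if (n_snps <= 0 || n_tag_snps < 0)
    stop("n_snps must be positive")
  if (n_snps < n_tag_snps)
    stop("n_snps is smaller than the number of tag sites requested")
  if (any(cn_allele_freqs < 0))
    stop("cn_allele_freqs must be non-negative")
  # published allele frequencies are rounded to 2 decimals and may miss 1
  # by up to 0.02; renormalize proportionally, reject anything worse
  if (abs(sum(cn_allele_freqs) - 1) > 0.02)
    stop("cn_allele_freqs must sum to 1 (within printed-rounding tolerance)")
  cn_allele_freqs <- cn_allele_freqs / sum(cn_allele_freqs)
  if (is.null(names(cn_allele_freqs)) ||
      anyNA(suppressWarnings(as.integer(names(cn_allele_freqs)))))
    stop("cn_allele_freqs must be named by integer haploid copy numbers")
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (expr_dispersion <= 0) stop("expr_dispersion must be positive")
  if (abs(sum(transcript_shares) - 1) > 1e-9 || any(transcript_shares < 0))
    stop("transcript_shares must be non-negative and sum to 1")
  if (length(cnv_interval) != 2 || cnv_interval[1] > cnv_interval[2])
    stop("cnv_interval must be [start, end] with start <= end")
  region_end <- region_start + region_span - 1
  if (cnv_interval[1] < region_start || cnv_interval[2] > region_end)
    stop("cnv_interval must lie within the simulated region")
  if (sweep_mean_length < 0 || neutral_mean_length <= 0)
    stop("segment length parameters must be positive (sweep may be 0)")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")

  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_trios = as.integer(n_trios),
    cn_allele_freqs = cn_allele_freqs,
    cn_alleles = as.integer(names(cn_allele_freqs)),
    mean_coverage = mean_coverage,
    n_snps = as.integer(n_snps),
    n_tag_snps = as.integer(n_tag_snps),
    region_start = region_start,
    region_end = region_end,
    region_span = region_span,
    cnv_interval = as.numeric(cnv_interval),
    sweep_mean_length = sweep_mean_length,
    neutral_mean_length = neutral_mean_length,
    n_founder_haps = as.integer(n_founder_haps),
    pool_divergence = pool_divergence,
    recomb_rate = recomb_rate,
    beta_mul = beta_mul,
    h2 = h2,
    expr_base_mean = expr_base_mean,
    expr_log_fc = expr_log_fc,
    expr_dispersion = expr_dispersion,
    transcript_shares = transcript_shares,
    n_null_genes = as.integer(n_null_genes),
    n_background_genes = as.integer(n_background_genes),
    libsize_sd = libsize_sd,
    depth_bin_bp = depth_bin_bp,
    flank_width = flank_width,
    overdispersion = overdispersion,
    seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic CNV cohort configuration\n")
  cat(sprintf("  %d individuals (%d trios), seed %d\n",
              x$n_individuals, x$n_trios, x$seed))
  cat(sprintf("  CN alleles {%s} at frequencies {%s}\n",
              paste(x$cn_alleles, collapse = ","),
              paste(format(x$cn_allele_freqs), collapse = ",")))
  cat(sprintf("  %.0fX coverage, %d SNPs (%d tag), CNV %s-%s\n",
              x$mean_coverage, x$n_snps, x$n_tag_snps,
              format(x$cnv_interval[1], big.mark = ","),
              format(x$cnv_interval[2], big.mark = ",")))
  invisible(x)
}

# Derive a per-stage 32-bit substream seed from the master seed so each
# generator is reproducible in isolation.
stage_seed <- function(cfg, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(cfg$seed) * 48271 + h * 65537) %%
               .Machine$integer.max)
}

# Run code under a stage substream, restoring the caller's RNG state.
with_stage_seed <- function(cfg, stage, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stage_seed(cfg, stage))
  force(code)
}
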