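#' Simulate a pedigree with parent-offspring trios
#'
#' Creates `n_trios` trios (two founder parents plus one child each) and
#' fills the cohort up to `n_individuals` with unrelated founders. If
#' `3 * n_trios` exceeds `n_individuals`, additional founders are created
#' as needed so every trio is complete.
#'
#' @param cfg a [sim_config()] object.
#' @return a `data.frame` of class `cnv_pedigree` with columns `id`,
#'   `sire`, `dam` (`NA` for founders), parents listed before children.
#' @examples
#' ped <- simulate_pedigree(sim_config(n_individuals = 10, n_trios = 2))
#' table(is.na(ped$sire))
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_total <- max(cfg$n_individuals, 3L * cfg$n_trios)
  ids <- sprintf("I%04d", seq_len(n_total))
  sire <- rep(NA_character_, n_total)
  dam <- rep(NA_character_, n_total)
  # first 2*n_trios individuals are trio parents, next n_trios are children,
  # the remainder unrelated founders
  if (cfg$n_trios > 0) {
    for (k in seq_len(cfg$n_trios)) {
      child <- 2L * cfg$n_trios + k
      sire[child] <- ids[2L * k - 1L]
      dam[child] <- ids[2L * k]
    }
  }
  ped <- data.frame(id = ids, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  class(ped) <- c("cnv_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree
#'
#' Checks for duplicated ids, parents that do not exist, and cycles
#' (an individual among its own ancestors).
#'
#' @param ped a pedigree `data.frame` with columns `id`, `sire`, `dam`.
#' @return the pedigree, invisibly, with a topological order attribute.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  parents <- c(ped$sire, ped$dam)
  known <- parents %in% ped$id | is.na(parents)
  if (!all(known))
    stop("pedigree references unknown parents: ",
         paste(unique(parents[!known]), collapse = ", "))
  ord <- pedigree_order(ped)   # errors on cycles
  attr(ped, "topo_order") <- ord
  invisible(ped)
}

# Topological order (parents before children); errors on cycles.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed & (si == 0L | placed[pmax(si, 1L)]) &
      (di == 0L | placed[pmax(di, 1L)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[!placed], collapse = ", "))
  ord
}

#' Draw haploid CNV alleles through a pedigree
#'
#' Founders draw two haploid copy-number alleles i.i.d. from
#' `cfg$cn_allele_freqs`; non-founders inherit one allele from each parent,
#' chosen uniformly among the parent's two. Transmission is therefore
#' Mendelian by construction.
#'
#' @param ped a pedigree from [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @return an integer matrix (individuals x 2, columns `pat`/`mat`,
#'   rownames ids) of haploid CN alleles. Attribute `transmitted` records,
#'   for non-founders, which parental haplotype (1 or 2) each gamete came
#'   from; used by [simulate_haplotype_panel()] to keep CNV alleles linked
#'   to their haplotypes.
#' @export
draw_cnv_alleles <- function(ped, cfg) {
  validate_pedigree(ped)
  ord <- pedigree_order(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  alleles <- matrix(NA_integer_, n, 2,
                    dimnames = list(ped$id, c("pat", "mat")))
  trans <- matrix(NA_integer_, n, 2,
                  dimnames = list(ped$id, c("pat", "mat")))
  with_stage_seed(cfg, "cnv_alleles", {
    for (i in ord) {
      for (side in 1:2) {
        par <- if (side == 1) ped$sire[i] else ped$dam[i]
        if (is.na(par)) {
          alleles[i, side] <- sample(cfg$cn_alleles, 1,
                                     prob = cfg$cn_allele_freqs)
        } else {
          j <- sample.int(2L, 1L)
          trans[i, side] <- j
          alleles[i, side] <- alleles[idx[par], j]
        }
      }
    }
  })
  attr(alleles, "transmitted") <- trans
  alleles
}

#' Mul (multiplicated-allele) dosage from haploid CN pairs
#'
#' Codes the CNV biallelically: haploid CN 1 is wildtype (Wt), any allele
#' in `mul_alleles` counts as multiplicated (Mul). The dosage is the number
#' of Mul alleles (0, 1 or 2).
#'
#' @param cn_pairs integer matrix of haploid allele pairs (individuals x 2).
#' @param mul_alleles haploid copy numbers counted as Mul.
#' @return named integer vector of Mul dosages.
#' @export
mul_dosage <- function(cn_pairs, mul_alleles = c(4L, 5L, 6L)) {
  d <- rowSums(matrix(cn_pairs %in% mul_alleles, nrow = nrow(cn_pairs)))
  stats::setNames(as.integer(d), rownames(cn_pairs))
}

#' Simulate read-depth profiles for the CNV interval and a flank
#'
#' Depth is accumulated in `depth_bin_bp` bins as Poisson counts with mean
#' `mean_coverage * local_copies / 2` per bin (optionally negative-binomial
#' when `cfg$overdispersion` is set) and averaged per region, emulating a
#' depth profiler that reports mean coverage of the CNV interval and of a
#' copy-neutral flank.
#'
#' @param cn_pairs haploid allele pairs from [draw_cnv_alleles()].
#' @param cfg a [sim_config()].
#' @return `data.frame` with columns `id`, `mean_depth_cnv`,
#'   `mean_depth_flank`, `fold_change`.
#' @export
simulate_depths <- function(cn_pairs, cfg) {
  n <- nrow(cn_pairs)
  width_cnv <- cfg$cnv_interval[2] - cfg$cnv_interval[1] + 1
  bins_cnv <- max(1L, floor(width_cnv / cfg$depth_bin_bp))
  bins_flank <- max(1L, floor(cfg$flank_width / cfg$depth_bin_bp))
  copies <- rowSums(cn_pairs)
  rbin <- function(k, mu) {
    if (is.null(cfg$overdispersion)) stats::rpois(k, mu)
    else stats::rnbinom(k, mu = mu, size = mu / (cfg$overdispersion - 1))
  }
  with_stage_seed(cfg, "depths", {
    cnv_depth <- vapply(seq_len(n), function(i)
      mean(rbin(bins_cnv, cfg$mean_coverage * copies[i] / 2)), 0)
    flank_depth <- vapply(seq_len(n), function(i)
      mean(rbin(bins_flank, cfg$mean_coverage)), 0)
  })
  data.frame(id = rownames(cn_pairs),
             mean_depth_cnv = cnv_depth,
             mean_depth_flank = flank_depth,
             fold_change = cnv_depth / flank_depth,
             stringsAsFactors = FALSE)
}

#' Simulate a phased haplotype panel with a CNV-linked selective sweep
#'
#' Background sites segregate at random frequencies on a mosaic of
#' `n_founder_haps` neutral founder haplotypes (exponential segment lengths,
#' mean `neutral_mean_length`). Every Mul-bearing haplotype (CN 4/5/6)
#' copies a single sweep founder haplotype over a core segment extending an
#' Exponential(`sweep_mean_length`) distance beyond each CNV boundary, so
#' all Mul haplotypes share a long identical core around the CNV. The
#' `n_tag_snps` intra-CNV tag sites carry the alternative allele on every
#' Mul haplotype and the reference allele on every Wt haplotype. Children
#' receive recombinant parental gametes consistent with the CN allele they
#' inherited in `cn_pairs`.
#'
#' @param ped pedigree; `cn_pairs` haploid alleles from
#'   [draw_cnv_alleles()] (with its `transmitted` attribute); `cfg` a
#'   [sim_config()].
#' @param ped,cn_pairs,cfg see description.
#' @return object of class `haplotype_panel`: list with `haplotypes`
#'   (0/1 integer matrix, 2 rows per individual, paternal first),
#'   `positions` (bp, strictly increasing), `ancestral` (per-site ancestral
#'   allele, all 0 here), `individuals`, `hap_cn` (haploid CN allele carried
#'   by each haplotype row), `tag_sites` (column indices), `cnv_interval`.
#' @export
simulate_haplotype_panel <- function(ped, cn_pairs, cfg) {
  validate_pedigree(ped)
  if (cfg$n_snps < cfg$n_tag_snps)
    stop("fewer sites than tag sites requested")
  trans <- attr(cn_pairs, "transmitted")
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  ord <- pedigree_order(ped)

  with_stage_seed(cfg, "panel", {
    ## site positions: tag sites inside the CNV, background outside
    n_bg <- cfg$n_snps - cfg$n_tag_snps
    tag_pos <- round(seq(cfg$cnv_interval[1] + 100,
                         cfg$cnv_interval[2] - 100,
                         length.out = cfg$n_tag_snps))
    bg_pos <- integer(0)
    while (length(bg_pos) < n_bg) {
      cand <- sample.int(cfg$region_span, n_bg - length(bg_pos)) +
        cfg$region_start - 1L
      cand <- cand[cand < cfg$cnv_interval[1] | cand > cfg$cnv_interval[2]]
      bg_pos <- unique(c(bg_pos, cand))
    }
    bg_pos <- sort(bg_pos)
    positions <- sort(c(tag_pos, bg_pos))
    m <- length(positions)
    tag_sites <- match(tag_pos, positions)

    ## ancestral haplotype pool: each new haplotype derives from a random
    ## earlier one with per-site divergence, so distinct ancestors are
    ## related (as sparse mutations make them in real panels) and EHH
    ## decays gradually rather than collapsing at the first site
    base_freq <- stats::runif(m, 0.2, 0.8)
    pool <- matrix(0L, cfg$n_founder_haps, m)
    pool[1, ] <- stats::rbinom(m, 1, base_freq)
    for (k in seq_len(cfg$n_founder_haps)[-1]) {
      parent <- sample.int(k - 1L, 1L)
      flip <- stats::rbinom(m, 1, cfg$pool_divergence) == 1L
      pool[k, ] <- ifelse(flip, 1L - pool[parent, ], pool[parent, ])
    }
    pool[, tag_sites] <- 0L
    sweep_hap <- pool[sample.int(cfg$n_founder_haps, 1L), ]
    flip <- stats::rbinom(m, 1, cfg$pool_divergence) == 1L
    sweep_hap <- ifelse(flip, 1L - sweep_hap, sweep_hap)
    sweep_hap[tag_sites] <- 1L

    # neutral mosaic over the pool
    neutral_hap <- function() {
      h <- integer(m)
      left <- cfg$region_start
      while (left <= cfg$region_end) {
        len <- stats::rexp(1, 1 / cfg$neutral_mean_length)
        right <- left + len
        sel <- positions >= left & positions < right
        if (any(sel)) h[sel] <- pool[sample.int(cfg$n_founder_haps, 1), sel]
        left <- right
      }
      h
    }
    mul_hap <- function() {
      h <- neutral_hap()
      core_l <- cfg$cnv_interval[1] -
        (if (cfg$sweep_mean_length > 0)
           stats::rexp(1, 1 / cfg$sweep_mean_length) else 0)
      core_r <- cfg$cnv_interval[2] +
        (if (cfg$sweep_mean_length > 0)
           stats::rexp(1, 1 / cfg$sweep_mean_length) else 0)
      sel <- positions >= core_l & positions <= core_r
      h[sel] <- sweep_hap[sel]
      h
    }
    meiosis <- function(h1, h2, want_idx) {
      n_x <- stats::rpois(1, cfg$recomb_rate * cfg$region_span)
      brk <- sort(stats::runif(n_x, cfg$region_start, cfg$region_end))
      seg <- findInterval(positions, brk)          # 0..n_x
      phase0 <- sample.int(2L, 1L)                 # haplotype on segment 0
      use1 <- (seg + phase0) %% 2L == 0L           # TRUE -> h1
      # which parental haplotype covers the CNV midpoint
      mid <- mean(cfg$cnv_interval)
      mid_seg <- findInterval(mid, brk)
      covers <- if ((mid_seg + phase0) %% 2L == 0L) 1L else 2L
      if (!is.na(want_idx) && covers != want_idx) use1 <- !use1
      ifelse(use1, h1, h2)
    }

    H <- matrix(NA_integer_, 2L * n, m)
    hap_cn <- integer(2L * n)
    for (i in ord) {
      for (side in 1:2) {
        row <- 2L * (i - 1L) + side
        hap_cn[row] <- cn_pairs[i, side]
        par <- if (side == 1) ped$sire[i] else ped$dam[i]
        if (is.na(par)) {
          H[row, ] <- if (cn_pairs[i, side] == 1L) neutral_hap() else mul_hap()
        } else {
          p <- idx[par]
          H[row, ] <- meiosis(H[2L * (p - 1L) + 1L, ],
                              H[2L * (p - 1L) + 2L, ],
                              trans[i, side])
        }
      }
    }
  })
  rownames(H) <- paste0(rep(ped$id, each = 2), c("_p", "_m"))
  structure(list(haplotypes = H,
                 positions = positions,
                 ancestral = integer(m),
                 individuals = ped$id,
                 hap_cn = hap_cn,
                 tag_sites = tag_sites,
                 cnv_interval = cfg$cnv_interval),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Phased haplotype panel: %d haplotypes (%d individuals), %d sites\n",
              nrow(x$haplotypes), length(x$individuals), ncol(x$haplotypes)))
  cat(sprintf("  positions %s-%s; %d tag sites in CNV %s-%s\n",
              format(min(x$positions), big.mark = ","),
              format(max(x$positions), big.mark = ","),
              length(x$tag_sites),
              format(x$cnv_interval[1], big.mark = ","),
              format(x$cnv_interval[2], big.mark = ",")))
  invisible(x)
}

#' Per-individual diploid dosages from a haplotype panel
#'
#' @param panel a `haplotype_panel`.
#' @return integer matrix (individuals x sites) of alternative-allele counts.
#' @export
panel_dosages <- function(panel) {
  H <- panel$haplotypes
  n <- length(panel$individuals)
  D <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
    H[seq(2, 2 * n, by = 2), , drop = FALSE]
  dimnames(D) <- list(panel$individuals,
                      paste0("v", seq_len(ncol(D))))
  D
}

#' Simulate per-site sequencing read counts with copy-proportional imbalance
#'
#' Inside the CNV interval each haplotype contributes reads in proportion
#' to its copy number, so a Wt/Mul heterozygote with Mul copy `c` has
#' expected alternative-allele read fraction `c / (c + 1)` at a site whose
#' alternative allele rides the Mul haplotype. Outside the CNV the expected
#' heterozygous fraction is 1/2. Totals are Poisson around coverage scaled
#' by local copy number; a base-calling error rate `error_rate` mixes the
#' two alleles.
#'
#' @param panel a `haplotype_panel`; `cn_pairs` matching haploid pairs;
#'   `cfg` a [sim_config()].
#' @param panel,cn_pairs,cfg see description.
#' @param error_rate per-read allele error probability.
#' @return object of class `site_read_counts`: list with integer matrices
#'   `ref` and `alt` (individuals x sites) and `positions`.
#' @export
simulate_site_read_counts <- function(panel, cn_pairs, cfg,
                                      error_rate = 0.001) {
  n <- length(panel$individuals)
  if (!identical(rownames(cn_pairs), panel$individuals))
    stop("panel and cn_pairs must cover the same individuals")
  m <- ncol(panel$haplotypes)
  in_cnv <- panel$positions >= panel$cnv_interval[1] &
    panel$positions <= panel$cnv_interval[2]
  H1 <- panel$haplotypes[seq(1, 2 * n, 2), , drop = FALSE]
  H2 <- panel$haplotypes[seq(2, 2 * n, 2), , drop = FALSE]
  c1 <- ifelse(in_cnv[col(H1)], cn_pairs[, 1][row(H1)], 1)
  c2 <- ifelse(in_cnv[col(H2)], cn_pairs[, 2][row(H2)], 1)
  total_copies <- c1 + c2
  alt_copies <- H1 * c1 + H2 * c2
  p_alt <- alt_copies / total_copies
  p_alt <- p_alt * (1 - error_rate) + (1 - p_alt) * error_rate
  with_stage_seed(cfg, "read_counts", {
    depth <- matrix(stats::rpois(n * m, cfg$mean_coverage * total_copies / 2),
                    n, m)
    alt <- matrix(stats::rbinom(n * m, as.vector(depth), as.vector(p_alt)),
                  n, m)
  })
  dimnames(depth) <- dimnames(alt) <-
    list(panel$individuals, paste0("site", seq_len(m)))
  structure(list(ref = depth - alt, alt = alt, positions = panel$positions),
            class = "site_read_counts")
}

#' Simulate a quantitative trait with a CNV-dosage effect
#'
#' `y = mu + beta_mul * MulDosage + g + e`, with the polygenic effect `g`
#' drawn with covariance proportional to the pedigree numerator relationship
#' matrix so that `var(g) / (var(g) + var(e)) = h2`, and equal residual
#' variances across individuals.
#'
#' @param cn_pairs haploid allele pairs; `ped` the pedigree; `cfg` a
#'   [sim_config()].
#' @param cn_pairs,ped,cfg see description.
#' @param mu overall mean.
#' @return `data.frame` with columns `id`, `y`, `mul_dosage` (truth).
#' @export
simulate_phenotype <- function(cn_pairs, ped, cfg, mu = 0) {
  if (cfg$h2 < 0 || cfg$h2 > 1) stop("h2 must lie in [0, 1]")
  A <- pedigree_amatrix(ped)
  n <- nrow(A)
  dos <- mul_dosage(cn_pairs)
  with_stage_seed(cfg, "phenotype", {
    L <- chol(A + diag(1e-8, n))
    g <- sqrt(cfg$h2) * drop(crossprod(L, stats::rnorm(n)))
    e <- sqrt(1 - cfg$h2) * stats::rnorm(n)
  })
  data.frame(id = ped$id,
             y = mu + cfg$beta_mul * dos[ped$id] + g + e,
             mul_dosage = as.integer(dos[ped$id]),
             stringsAsFactors = FALSE)
}

#' Pedigree numerator relationship matrix
#'
#' Wright's additive relationship matrix computed recursively
#' (parents before offspring).
#'
#' @param ped a pedigree `data.frame`.
#' @return symmetric numeric matrix with dimnames the individual ids.
#' @export
pedigree_amatrix <- function(ped) {
  validate_pedigree(ped)
  ord <- pedigree_order(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    s <- if (is.na(ped$sire[i])) 0L else idx[ped$sire[i]]
    d <- if (is.na(ped$dam[i])) 0L else idx[ped$dam[i]]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    others <- setdiff(ord[seq_len(which(ord == i) - 1L)], i)
    if (length(others)) {
      val <- 0.5 * ((if (s > 0) A[others, s] else 0) +
                      (if (d > 0) A[others, d] else 0))
      A[i, others] <- A[others, i] <- val
    }
  }
  A
}

#' Simulate negative-binomial expression with a CN-dosage cis effect
#'
#' One focal gene's log-mean increases by `expr_log_fc` per copy of the CNV
#' segment above the diploid baseline; `n_null_genes` neighbouring genes
#' have no CN effect. The focal gene is split into a canonical and an
#' alternative transcript at baseline shares `transcript_shares` (98%/2%
#' by default; only the alternative transcript contains the CNV-overlapping
#' exon). Counts are negative binomial with lognormal per-sample library
#' sizes.
#'
#' @param cn_pairs haploid allele pairs (expression is simulated for every
#'   row); `cfg` a [sim_config()].
#' @param cn_pairs,cfg see description.
#' @return object of class `expression_sim`: list with `gene_counts`
#'   (genes x samples), `transcript_counts` (focal transcripts x samples),
#'   `features` (annotation: feature, chrom, start, end), `lib_size`
#'   (true library-size factors), `cn_dosage` (total copies per sample).
#' @export
simulate_expression <- function(cn_pairs, cfg) {
  if (cfg$expr_dispersion <= 0) stop("dispersion must be positive")
  ids <- rownames(cn_pairs)
  n <- length(ids)
  copies <- rowSums(cn_pairs)
  size <- 1 / cfg$expr_dispersion
  n_genes <- cfg$n_null_genes + cfg$n_background_genes + 1L
  gene_names <- c("GC", sprintf("NBR%02d", seq_len(cfg$n_null_genes)),
                  if (cfg$n_background_genes > 0)
                    sprintf("BG%03d", seq_len(cfg$n_background_genes)))
  with_stage_seed(cfg, "expression", {
    lib <- exp(stats::rnorm(n, 0, cfg$libsize_sd))
    lib <- lib / exp(mean(log(lib)))
    base <- c(cfg$expr_base_mean,
              exp(stats::runif(n_genes - 1L, log(50), log(2000))))
    mu <- outer(base, lib)
    mu[1, ] <- mu[1, ] * exp(cfg$expr_log_fc * (copies - 2))
    counts <- matrix(stats::rnbinom(n_genes * n, mu = as.vector(mu),
                                    size = size), n_genes, n)
    shares <- cfg$transcript_shares
    mu_tx <- rbind(mu[1, ] * shares[1], mu[1, ] * shares[2])
    tx <- matrix(stats::rnbinom(2L * n, mu = as.vector(mu_tx), size = size),
                 2L, n)
  })
  dimnames(counts) <- list(gene_names, ids)
  dimnames(tx) <- list(c("GC_canonical", "GC_alternative"), ids)
  cnv_mid <- round(mean(cfg$cnv_interval))
  n_cis <- cfg$n_null_genes + 1L
  feat_pos <- round(seq(cfg$cnv_interval[1] - 9e5, cfg$cnv_interval[2] + 9e5,
                        length.out = n_cis))
  features <- data.frame(
    feature = gene_names,
    chrom = c(rep("6", n_cis), rep("5", cfg$n_background_genes)),
    start = c(cnv_mid - 25000, feat_pos[-1] - 10000,
              seq_len(cfg$n_background_genes) * 1e6),
    end = c(cnv_mid, feat_pos[-1] + 10000,
            seq_len(cfg$n_background_genes) * 1e6 + 20000),
    stringsAsFactors = FALSE)
  structure(list(gene_counts = counts, transcript_counts = tx,
                 features = features, lib_size = lib,
                 cn_dosage = stats::setNames(copies, ids)),
            class = "expression_sim")
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining the individual generators under one
#' configuration: pedigree, haploid CNV alleles, depth profiles, phased
#' haplotype panel, per-site read counts, quantitative trait, and
#' expression counts. Each stage uses its own seed substream derived from
#' `cfg$seed`, so the full cohort is reproducible byte-for-byte.
#'
#' @param cfg a [sim_config()].
#' @return list of class `cnv_cohort` with elements `config`, `pedigree`,
#'   `cn_pairs`, `depths`, `panel`, `read_counts`, `trait`, `expression`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 24, n_trios = 6,
#'                                   n_snps = 50, seed = 7))
#' names(coh)
#' @export
simulate_cohort <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  cn <- draw_cnv_alleles(ped, cfg)
  structure(list(
    config = cfg,
    pedigree = ped,
    cn_pairs = cn,
    depths = simulate_depths(cn, cfg),
    panel = (panel <- simulate_haplotype_panel(ped, cn, cfg)),
    read_counts = simulate_site_read_counts(panel, cn, cfg),
    trait = simulate_phenotype(cn, ped, cfg),
    expression = simulate_expression(cn, cfg)
  ), class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CNV cohort: %d individuals (%d trios), %d sites, seed %d\n",
              nrow(x$pedigree), x$config$n_trios,
              length(x$panel$positions), x$config$seed))
  invisible(x)
}
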