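test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_individuals = 0), "positive")
  expect_error(sim_config(n_snps = 3, n_tag_snps = 5), "tag sites")
  expect_error(sim_config(cn_allele_freqs = c("1" = 0.5, "4" = 0.4)),
               "sum to 1")
  expect_error(sim_config(cn_allele_freqs = c("1" = -0.1, "4" = 1.1)),
               "non-negative")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(expr_dispersion = 0), "dispersion")
  expect_error(sim_config(cnv_interval = c(1e6, 2e6)), "within")
  expect_error(sim_config(transcript_shares = c(0.9, 0.2)), "sum to 1")
  # printed rounding of published frequencies is renormalized exactly
  cfg <- sim_config()
  expect_equal(sum(cfg$cn_allele_freqs), 1, tolerance = 1e-12)
})

test_that("pedigree generator creates the requested trios plus founders", {
  ped0 <- simulate_pedigree(test_cfg(n_individuals = 10, n_trios = 0))
  expect_equal(nrow(ped0), 10)
  expect_true(all(is.na(ped0$sire)) && all(is.na(ped0$dam)))

  # 80 trios as in a 240-animal trio set, inside a 266-animal cohort
  ped <- simulate_pedigree(sim_config(n_individuals = 266, n_trios = 80))
  expect_equal(nrow(ped), 266)
  children <- !is.na(ped$sire) & !is.na(ped$dam)
  expect_equal(sum(children), 80)
  trio_members <- unique(c(ped$id[children], ped$sire[children],
                           ped$dam[children]))
  expect_equal(length(trio_members), 240)
  expect_identical(ped, simulate_pedigree(sim_config(n_individuals = 266,
                                                     n_trios = 80)))
})

test_that("pedigree validation catches cycles and unknown parents", {
  bad <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(validate_pedigree(bad), "cycle")
  bad2 <- data.frame(id = "a", sire = "ghost", dam = NA)
  expect_error(validate_pedigree(bad2), "unknown")
  # order-independence: child listed before its parents is fine
  ok <- data.frame(id = c("c", "a", "b"), sire = c("a", NA, NA),
                   dam = c("b", NA, NA), stringsAsFactors = FALSE)
  expect_silent(validate_pedigree(ok))
})

test_that("CNV alleles are Mendelian by construction and frequencies recover", {
  # degenerate frequency: everyone (1,1)
  cfg1 <- test_cfg(cn_allele_freqs = c("1" = 1))
  ped1 <- simulate_pedigree(cfg1)
  cn1 <- draw_cnv_alleles(ped1, cfg1)
  expect_true(all(cn1 == 1L))

  # child alleles always one from each parent (checked over many trios)
  cfg <- test_cfg(n_individuals = 120, n_trios = 40, seed = 3)
  ped <- simulate_pedigree(cfg)
  cn <- draw_cnv_alleles(ped, cfg)
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  for (k in which(!is.na(ped$sire))) {
    expect_true(cn[k, 1] %in% cn[idx[ped$sire[k]], ])
    expect_true(cn[k, 2] %in% cn[idx[ped$dam[k]], ])
  }

  # founder allele frequencies recover within binomial 99% intervals
  cfg2 <- sim_config(n_individuals = 266, n_trios = 80, seed = 11)
  ped2 <- simulate_pedigree(cfg2)
  cn2 <- draw_cnv_alleles(ped2, cfg2)
  founders <- is.na(ped2$sire)
  alleles <- c(cn2[founders, ])
  for (a in names(cfg2$cn_allele_freqs)) {
    p <- cfg2$cn_allele_freqs[[a]]
    phat <- mean(alleles == as.integer(a))
    half <- qnorm(0.995) * sqrt(p * (1 - p) / length(alleles))
    expect_lt(abs(phat - p), max(half, 0.005) + 1e-9)
  }

  expect_identical(cn, draw_cnv_alleles(ped, cfg))
})

test_that("depth profiles scale as coverage times half the diploid copies", {
  cfg <- test_cfg(seed = 7)
  pairs <- rbind(matrix(rep(c(1L, 1L), 400), ncol = 2, byrow = TRUE),
                 matrix(rep(c(4L, 4L), 400), ncol = 2, byrow = TRUE),
                 matrix(rep(c(4L, 6L), 400), ncol = 2, byrow = TRUE))
  rownames(pairs) <- sprintf("X%04d", seq_len(nrow(pairs)))
  dp <- simulate_depths(pairs, cfg)
  grp <- rep(c("11", "44", "46"), each = 400)
  means <- tapply(dp$mean_depth_cnv, grp, mean)
  ses <- tapply(dp$mean_depth_cnv, grp, function(x) sd(x) / sqrt(length(x)))
  expected <- c("11" = 26, "44" = 104, "46" = 130)
  for (g in names(expected))
    expect_lt(abs(means[[g]] - expected[[g]]), 3 * ses[[g]] + 1e-9)
  expect_true(all(dp$fold_change > 0))
})

test_that("haplotype panel links tag sites perfectly to the Mul class", {
  cfg <- test_cfg(seed = 2)
  ped <- simulate_pedigree(cfg)
  cn <- draw_cnv_alleles(ped, cfg)
  panel <- simulate_haplotype_panel(ped, cn, cfg)

  expect_equal(nrow(panel$haplotypes), 2 * nrow(ped))
  expect_true(all(diff(panel$positions) > 0))
  expect_equal(length(panel$tag_sites), cfg$n_tag_snps)

  mul_hap <- panel$hap_cn > 1
  for (s in panel$tag_sites) {
    expect_true(all(panel$haplotypes[mul_hap, s] == 1L))
    expect_true(all(panel$haplotypes[!mul_hap, s] == 0L))
  }
  # biallelic recoding of the CNV is in perfect LD with each tag column
  dos <- panel_dosages(panel)
  md <- mul_dosage(cn)
  for (s in panel$tag_sites)
    expect_equal(cor(md, dos[, s])^2, 1, tolerance = 1e-12)

  expect_error(simulate_haplotype_panel(ped, cn,
                                        test_cfg(n_snps = 5, n_tag_snps = 5)),
               NA)  # exactly equal counts allowed
})

test_that("read counts show copy-proportional allelic imbalance", {
  cfg <- test_cfg(n_individuals = 200, n_trios = 0, seed = 6,
                  cn_allele_freqs = c("1" = 0.5, "4" = 0.3, "6" = 0.2))
  ped <- simulate_pedigree(cfg)
  cn <- draw_cnv_alleles(ped, cfg)
  panel <- simulate_haplotype_panel(ped, cn, cfg)
  counts <- simulate_site_read_counts(panel, cn, cfg, error_rate = 0)

  frac_at_tags <- function(sel) {
    a <- counts$alt[sel, panel$tag_sites, drop = FALSE]
    r <- counts$ref[sel, panel$tag_sites, drop = FALSE]
    sum(a) / sum(a + r)
  }
  pair_is <- function(a, b) cn[, 1] == a & cn[, 2] == b |
    cn[, 1] == b & cn[, 2] == a
  expect_equal(frac_at_tags(pair_is(1, 4)), 4 / 5, tolerance = 0.03)
  expect_equal(frac_at_tags(pair_is(1, 6)), 6 / 7, tolerance = 0.03)

  # non-CNV heterozygous sites balance at 1/2
  dos <- panel_dosages(panel)
  bg <- setdiff(seq_along(panel$positions), panel$tag_sites)[1:40]
  het <- dos[, bg, drop = FALSE] == 1
  a <- counts$alt[, bg, drop = FALSE]
  r <- counts$ref[, bg, drop = FALSE]
  expect_equal(sum(a[het]) / sum(a[het] + r[het]), 0.5, tolerance = 0.02)
})

test_that("trait carries the configured Mul-dosage effect", {
  cfg <- test_cfg(n_individuals = 400, n_trios = 100, beta_mul = 0.8,
                  h2 = 0.3, seed = 9)
  ped <- simulate_pedigree(cfg)
  cn <- draw_cnv_alleles(ped, cfg)
  tr <- simulate_phenotype(cn, ped, cfg)
  fitlm <- lm(tr$y ~ tr$mul_dosage)
  expect_equal(unname(coef(fitlm)[2]), 0.8, tolerance = 0.25)

  # null configuration: no dosage association, unit-ish variance
  cfg0 <- test_cfg(n_individuals = 400, n_trios = 0, beta_mul = 0, h2 = 0,
                   seed = 9)
  ped0 <- simulate_pedigree(cfg0)
  cn0 <- draw_cnv_alleles(ped0, cfg0)
  tr0 <- simulate_phenotype(cn0, ped0, cfg0)
  expect_gt(summary(lm(tr0$y ~ tr0$mul_dosage))$coefficients[2, 4], 0.001)
  expect_equal(sd(tr0$y), 1, tolerance = 0.15)
  expect_error(simulate_phenotype(cn0, ped0, test_cfg(h2 = 2)), "h2")

  expect_identical(tr, simulate_phenotype(cn, ped, cfg))
})

test_that("expression counts carry the CN-dosage cis effect and 98/2 shares", {
  cfg <- test_cfg(n_individuals = 250, n_trios = 0, seed = 14)
  ped <- simulate_pedigree(cfg)
  cn <- draw_cnv_alleles(ped, cfg)
  ex <- simulate_expression(cn, cfg)
  copies <- rowSums(cn)
  gc <- ex$gene_counts["GC", ]

  # higher CN dosage -> higher focal expression
  lo <- copies == 2; hi <- copies >= 8
  expect_gt(mean(gc[hi]), mean(gc[lo]) * exp(0.08 * 6) * 0.8)
  # null neighbour shows no dosage trend
  p_null <- summary(lm(log1p(ex$gene_counts["NBR04", ]) ~ copies))$coefficients[2, 4]
  expect_gt(p_null, 0.001)
  # alternative transcript ~2% of the focal gene total
  tx <- ex$transcript_counts
  share <- sum(tx["GC_alternative", ]) / sum(colSums(tx))
  expect_lt(abs(share - 0.02), 0.005)

  # dosage effect switched off: no trend
  cfg0 <- test_cfg(n_individuals = 250, n_trios = 0, seed = 14,
                   expr_log_fc = 0)
  ex0 <- simulate_expression(cn, cfg0)
  p0 <- summary(lm(log1p(ex0$gene_counts["GC", ]) ~ copies))$coefficients[2, 4]
  expect_gt(p0, 0.001)
})

test_that("whole cohorts are byte-identical under a fixed seed", {
  cfg <- test_cfg(n_individuals = 30, n_trios = 8, n_snps = 60, seed = 21)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(test_cfg(n_individuals = 30, n_trios = 8,
                                 n_snps = 60, seed = 22))
  expect_false(identical(c1$panel$haplotypes, c3$panel$haplotypes))
})
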