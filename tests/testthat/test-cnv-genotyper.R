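test_that("diploid CN calling rounds twice the fold change", {
  prof <- data.frame(id = c("a", "b", "c", "d"),
                     mean_depth_cnv = c(26, 104, 130, 32.5),
                     mean_depth_flank = c(26, 26, 26, 26))
  calls <- call_diploid_cn(prof)
  expect_equal(calls$diploid_cn, c(2L, 8L, 10L, 3L))  # 2*1.25 ties away from 0
  expect_equal(calls$fold_change, c(1, 4, 5, 1.25))
  expect_error(call_diploid_cn(data.frame(id = "x", mean_depth_cnv = 10,
                                          mean_depth_flank = 0)),
               "unusable")
})

test_that("allele-pair enumeration matches the possible combinations", {
  expect_equal(enumerate_allele_pairs(10), cbind(a = c(4L, 5L), b = c(6L, 5L)),
               ignore_attr = TRUE)
  expect_equal(enumerate_allele_pairs(2), cbind(a = 1L, b = 1L),
               ignore_attr = TRUE)
  expect_equal(nrow(enumerate_allele_pairs(3)), 0)
  expect_equal(enumerate_allele_pairs(12), cbind(a = 6L, b = 6L),
               ignore_attr = TRUE)
  expect_equal(nrow(enumerate_allele_pairs(4, A = c(1, 2, 3))), 2)  # (1,3),(2,2)
})

test_that("pedigree resolution deduces CN10 carriers and flags the rest", {
  # sire d=5 -> (1,4); dam d=7 -> (1,6); child d=10 must be (4,6)
  ped <- data.frame(id = c("S", "D", "C"), sire = c(NA, NA, "S"),
                    dam = c(NA, NA, "D"), stringsAsFactors = FALSE)
  res <- resolve_pedigree_cn(ped, c(S = 5L, D = 7L, C = 10L))
  g <- res$genotypes
  expect_true(all(g$resolved))
  expect_equal(unlist(g[g$id == "C", c("allele1", "allele2")]),
               c(allele1 = 4L, allele2 = 6L))
  expect_equal(res$mendel$n_incompatible, 0)

  # isolated d=10 individual stays unresolved with both candidates
  ped1 <- data.frame(id = "X", sire = NA_character_, dam = NA_character_)
  res1 <- resolve_pedigree_cn(ped1, c(X = 10L))
  expect_false(res1$genotypes$resolved)
  expect_equal(res1$genotypes$n_candidates, 2L)

  # all-founder cohort with d=2 everywhere resolves uniquely
  ped2 <- data.frame(id = letters[1:5], sire = NA_character_,
                     dam = NA_character_)
  res2 <- resolve_pedigree_cn(ped2, setNames(rep(2L, 5), letters[1:5]))
  expect_true(all(res2$genotypes$resolved))
  expect_true(all(res2$genotypes$allele1 == 1 & res2$genotypes$allele2 == 1))
  expect_equal(res2$mendel$n_incompatible, 0)

  # homozygous-parent shortcut: sire d=8 is (4,4), so child d=10 is (4,6)
  res3 <- resolve_pedigree_cn(
    data.frame(id = c("S", "C"), sire = c(NA, "S"), dam = c(NA, NA)),
    c(S = 8L, C = 10L))
  gc3 <- res3$genotypes[res3$genotypes$id == "C", ]
  expect_true(gc3$resolved)
  expect_equal(c(gc3$allele1, gc3$allele2), c(4L, 6L))
})

test_that("resolver equals exhaustive brute force on an exhaustive trio grid", {
  ds <- c(2L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, NA)
  ped <- data.frame(id = c("S", "D", "C"), sire = c(NA, NA, "S"),
                    dam = c(NA, NA, "D"), stringsAsFactors = FALSE)
  n_unsat <- 0
  for (s in ds) for (d in ds) for (ch in c(2L, 7L, 10L, 11L)) {
    dip <- c(S = s, D = d, C = ch)
    res <- resolve_pedigree_cn(ped, dip)
    want <- brute_force_resolve(ped, dip)
    if (!attr(want, "satisfiable")) {
      # impossible configurations must surface as incompatible trios
      n_unsat <- n_unsat + 1
      expect_gte(res$mendel$n_incompatible, 1)
      next
    }
    for (id in ped$id) {
      g <- res$candidates[[id]]; w <- want[[id]]
      expect_equal(g[order(g[, 1], g[, 2]), , drop = FALSE],
                   w[order(w[, 1], w[, 2]), , drop = FALSE],
                   ignore_attr = TRUE,
                   label = sprintf("S=%s D=%s C=%s id=%s", s, d, ch, id))
    }
  }
  expect_gt(n_unsat, 0)
})

test_that("resolver equals brute force on random multi-child families", {
  set.seed(42)
  A <- c(1L, 4L, 5L, 6L)
  for (rep in 1:20) {
    n_kids <- sample(1:3, 1)
    grand <- sample(c(TRUE, FALSE), 1)
    ids <- c(if (grand) c("GS", "GD"), "S", "D",
             paste0("C", seq_len(n_kids)))
    ped <- data.frame(id = ids, sire = NA_character_,
                      dam = NA_character_, stringsAsFactors = FALSE)
    if (grand) { ped$sire[ped$id == "S"] <- "GS"; ped$dam[ped$id == "S"] <- "GD" }
    ped$sire[grepl("^C", ped$id)] <- "S"
    ped$dam[grepl("^C", ped$id)] <- "D"
    # draw true alleles through the pedigree, then corrupt/missing some
    truth <- list()
    for (i in seq_len(nrow(ped))) {
      s <- ped$sire[i]; d <- ped$dam[i]
      truth[[ped$id[i]]] <- c(
        if (is.na(s)) sample(A, 1) else sample(truth[[s]], 1),
        if (is.na(d)) sample(A, 1) else sample(truth[[d]], 1))
    }
    dip <- vapply(truth, sum, 1L)[ped$id]
    miss <- runif(length(dip)) < 0.2
    dip[miss] <- NA
    got <- resolve_pedigree_cn(ped, dip)$candidates
    want <- brute_force_resolve(ped, dip)
    for (id in ped$id) {
      g <- got[[id]]; w <- want[[id]]
      expect_equal(g[order(g[, 1], g[, 2]), , drop = FALSE],
                   w[order(w[, 1], w[, 2]), , drop = FALSE],
                   ignore_attr = TRUE, label = paste("rep", rep, "id", id))
    }
  }
})

test_that("simulated cohorts genotype accurately and Mendel-cleanly", {
  cfg <- sim_config(n_individuals = 150, n_trios = 45, n_snps = 20, seed = 31)
  ped <- simulate_pedigree(cfg)
  cn <- draw_cnv_alleles(ped, cfg)
  calls <- call_diploid_cn(simulate_depths(cn, cfg))
  expect_gte(mean(calls$diploid_cn == rowSums(cn)), 0.99)

  res <- resolve_pedigree_cn(ped, calls)
  expect_equal(res$mendel$n_incompatible, 0)
  g <- res$genotypes
  # resolved pairs match the simulated truth
  for (i in which(g$resolved))
    expect_equal(sort(c(g$allele1[i], g$allele2[i])), sort(cn[i, ]),
                 ignore_attr = TRUE)
  # resolved candidates are always among the depth-implied enumeration
  for (i in seq_len(nrow(g))) {
    cand <- res$candidates[[i]]
    enum <- enumerate_allele_pairs(g$diploid_cn[i])
    if (nrow(cand) > 0)
      expect_true(all(apply(cand, 1, function(p)
        any(enum[, 1] == p[1] & enum[, 2] == p[2]))))
  }

  # every diploid-CN-10 individual with a resolved parent becomes (4,6)
  cfg2 <- sim_config(n_individuals = 240, n_trios = 80, n_snps = 20,
                     cn_allele_freqs = c("1" = 0.25, "4" = 0.45,
                                         "5" = 0.1, "6" = 0.2),
                     seed = 33)
  ped2 <- simulate_pedigree(cfg2)
  cn2 <- draw_cnv_alleles(ped2, cfg2)
  res2 <- resolve_pedigree_cn(ped2, call_diploid_cn(simulate_depths(cn2, cfg2)))
  g2 <- res2$genotypes
  idx <- setNames(seq_len(nrow(ped2)), ped2$id)
  checked <- 0
  for (i in which(g2$diploid_cn == 10)) {
    truth46 <- setequal(cn2[i, ], c(4, 6))
    par_res <- c(ped2$sire[i], ped2$dam[i])
    par_res <- par_res[!is.na(par_res)]
    # a parent is informative for a CN10 child when it is resolved and
    # carries no 5-allele: the (5,5) decomposition then needs a 5 from
    # that parent and is excluded, forcing (4,6)
    informative <- any(vapply(idx[par_res], function(p)
      g2$resolved[p] && !(5 %in% c(g2$allele1[p], g2$allele2[p])), TRUE))
    if (truth46 && informative) {
      checked <- checked + 1
      expect_true(g2$resolved[i])
      expect_equal(sort(c(g2$allele1[i], g2$allele2[i])), c(4L, 6L))
    }
  }
  expect_gt(checked, 0)
})

test_that("Mendelian checking flags exactly the corrupted trios", {
  ped <- data.frame(id = c("S", "D", "C"), sire = c(NA, NA, "S"),
                    dam = c(NA, NA, "D"), stringsAsFactors = FALSE)
  ok <- resolve_pedigree_cn(ped, c(S = 2L, D = 2L, C = 2L))
  expect_equal(ok$mendel$n_incompatible, 0)
  bad <- resolve_pedigree_cn(ped, c(S = 2L, D = 2L, C = 5L))  # (1,4) child
  expect_equal(bad$mendel$n_incompatible, 1)
  expect_equal(bad$mendel$trios$status, "incompatible")

  # corrupting k trio children in a clean cohort yields k incompatibilities
  cfg <- sim_config(n_individuals = 120, n_trios = 40, n_snps = 20,
                    cn_allele_freqs = c("1" = 0.6, "4" = 0.4), seed = 5)
  ped2 <- simulate_pedigree(cfg)
  cn2 <- draw_cnv_alleles(ped2, cfg)
  dip <- setNames(rowSums(cn2), ped2$id)
  kids <- ped2$id[!is.na(ped2$sire)]
  corrupt <- kids[1:3]
  # parents only carry alleles {1,4}, so a (5,6) child is impossible
  for (ch in corrupt) dip[ch] <- 11L                  # forces (5,6)
  res <- resolve_pedigree_cn(ped2, dip)
  expect_equal(res$mendel$n_incompatible, 3)
})

test_that("allelic-imbalance correction repairs injected miscalls", {
  # single constructed case: AD 4/21 on a (1,4) heterozygote called Alt/Alt
  cfg <- test_cfg(seed = 4)
  coh <- simulate_cohort(cfg)
  res <- resolve_pedigree_cn(coh$pedigree,
                             call_diploid_cn(coh$depths))
  G <- panel_dosages(coh$panel)
  tag <- coh$panel$tag_sites
  het14 <- which(apply(coh$cn_pairs, 1, function(p) setequal(p, c(1, 4))))[1]
  id14 <- rownames(coh$cn_pairs)[het14]
  counts <- coh$read_counts
  counts$ref[id14, tag[1]] <- 4L
  counts$alt[id14, tag[1]] <- 21L
  Gbad <- G
  Gbad[id14, tag[1]] <- 2L                           # miscalled Alt/Alt
  fix <- suppressWarnings(
    correct_imbalanced_genotypes(counts, Gbad, res, ped = coh$pedigree,
                                 cnv_sites = tag))
  corr <- fix$corrections[fix$corrections$id == id14, ]
  expect_equal(nrow(corr), 1)
  expect_equal(corr$before, 2L)
  expect_equal(corr$after, 1L)
  expect_equal(corr$expected_alt_fraction, 0.8, tolerance = 0.02)

  # three injected errors across the cohort are all found and fixed
  dos <- mul_dosage(coh$cn_pairs)
  hets <- names(dos)[dos == 1]
  pick <- hets[1:3]
  Gbad3 <- G
  for (k in 1:3) Gbad3[pick[k], tag[k]] <- 2L
  fix3 <- suppressWarnings(
    correct_imbalanced_genotypes(coh$read_counts, Gbad3, res,
                                 ped = coh$pedigree, cnv_sites = tag))
  expect_identical(fix3$genotypes, G)
  expect_setequal(fix3$corrections$id, pick)

  # correction never increases site-level trio Mendelian errors
  for (s in tag) {
    expect_lte(trio_gt_errors(fix3$genotypes, coh$pedigree, s),
               trio_gt_errors(Gbad3, coh$pedigree, s))
  }
  # genotypes outside the CNV are untouched
  bg <- setdiff(seq_along(coh$panel$positions), tag)
  expect_identical(fix3$genotypes[, bg], G[, bg])
})

test_that("tag-SNP discovery ranks perfect proxies first", {
  set.seed(8)
  n <- 100
  md <- rbinom(n, 2, 0.5)
  dos <- cbind(tag = md,                         # perfect proxy
               near = ifelse(runif(n) < 0.02, 2 - md, md),
               indep = rbinom(n, 2, 0.5),
               mono = rep(1L, n))
  pos <- c(100, 200, 300, 400)
  expect_warning(
    tags <- find_tag_snps(dos, md, pos, cnv_interval = c(50, 250),
                          r2_threshold = 0.9),
    "zero-variance")
  expect_equal(tags$position[1], 100)
  expect_equal(tags$r2[1], 1, tolerance = 1e-12)
  expect_true(all(tags$r2 >= 0.9))
  expect_false(300 %in% tags$position)
  expect_true(tags$in_cnv[tags$position == 100])
  suppressWarnings(
    expect_equal(nrow(find_tag_snps(dos, md, pos, r2_threshold = 0.999999)), 1))
  expect_error(find_tag_snps(dos, rep(1, n), pos), "zero variance")
})
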