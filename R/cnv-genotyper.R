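#' Call diploid copy number from depth fold change
#'
#' The diploid copy number is `round(2 * FC)` with
#' `FC = mean_depth_cnv / mean_depth_flank`, ties rounded half away from
#' zero (so FC 1.25 -> CN 3). Matches reading integer peaks off a
#' fold-change histogram; no mixture clustering is attempted.
#'
#' @param profile `data.frame` with columns `id`, `mean_depth_cnv`,
#'   `mean_depth_flank` (e.g. from [simulate_depths()]).
#' @return `data.frame` with columns `id`, `fold_change`, `diploid_cn`.
#' @examples
#' call_diploid_cn(data.frame(id = "a", mean_depth_cnv = 130,
#'                            mean_depth_flank = 26))
#' @export
call_diploid_cn <- function(profile) {
  if (any(profile$mean_depth_flank <= 0))
    stop("unusable sample: non-positive flank depth for ",
         paste(profile$id[profile$mean_depth_flank <= 0], collapse = ", "))
  fc <- profile$mean_depth_cnv / profile$mean_depth_flank
  data.frame(id = profile$id,
             fold_change = fc,
             diploid_cn = as.integer(floor(2 * fc + 0.5)),
             stringsAsFactors = FALSE)
}

#' Enumerate unordered haploid allele pairs for a diploid copy number
#'
#' Returns every pair `(a, b)` with `a <= b`, both in the allele set `A`,
#' summing to the diploid copy number `d`. The empty set is a valid result
#' (e.g. `d = 3` cannot be decomposed over `{1, 4, 5, 6}`).
#'
#' @param d diploid copy number (non-negative integer).
#' @param A haploid allele set (positive integers), default `c(1, 4, 5, 6)`.
#' @return integer matrix with columns `a`, `b`; zero rows when no
#'   decomposition exists.
#' @examples
#' enumerate_allele_pairs(10)   # (4,6) and (5,5)
#' @export
enumerate_allele_pairs <- function(d, A = c(1L, 4L, 5L, 6L)) {
  stopifnot(d >= 0, length(A) >= 1, all(A > 0))
  A <- sort(unique(as.integer(A)))
  pairs <- expand.grid(a = A, b = A)
  pairs <- pairs[pairs$a <= pairs$b & pairs$a + pairs$b == d, , drop = FALSE]
  as.matrix(pairs[order(pairs$a), , drop = FALSE])
}

# Internal: candidate list per individual from diploid CNs (NA -> all pairs)
.candidate_sets <- function(diploid_cn, A) {
  all_pairs <- do.call(rbind, lapply(unique(stats::na.omit(diploid_cn)),
                                     function(d) enumerate_allele_pairs(d, A)))
  lapply(diploid_cn, function(d) {
    if (is.na(d)) {
      ap <- expand.grid(a = A, b = A)
      as.matrix(ap[ap$a <= ap$b, , drop = FALSE])
    } else enumerate_allele_pairs(d, A)
  })
}

# Can a child pair (ca, cb) be formed from one allele of pair p1 and one of p2?
.pair_compatible <- function(child, p1, p2) {
  (child[1] %in% p1 && child[2] %in% p2) ||
    (child[2] %in% p1 && child[1] %in% p2)
}

#' Resolve haploid CNV alleles through the pedigree
#'
#' Starting from the candidate allele pairs implied by each individual's
#' diploid copy number, runs constraint propagation to a fixpoint: a
#' child's pair must be formable from one allele of some surviving pair of
#' each genotyped parent, and a parent's pair must be able to supply every
#' genotyped child jointly with the other parent. Within each connected
#' family component of at most `max_component` members, an exhaustive joint
#' enumeration then finalizes assignments (keeping exactly the candidates
#' that occur in some globally consistent configuration). Individuals whose
#' candidate set remains larger than one are reported unresolved, never
#' guessed. Trios with no satisfying joint assignment are flagged
#' incompatible in the accompanying [check_mendelian()] report, not raised
#' as errors.
#'
#' @param ped pedigree `data.frame` (`id`, `sire`, `dam`).
#' @param diploid_cn named integer vector of diploid copy numbers
#'   (`NA` = missing), names matching `ped$id`, or the `data.frame`
#'   returned by [call_diploid_cn()].
#' @param A haploid allele set.
#' @param max_component maximum family-component size for exhaustive
#'   enumeration (larger components keep the propagation fixpoint only).
#' @return list of class `cn_genotypes` with elements `genotypes` (a
#'   `data.frame`: `id`, `diploid_cn`, `n_candidates`, `resolved` flag,
#'   `allele1`, `allele2` (NA when unresolved), `mul_dosage`),
#'   `candidates` (named list of candidate matrices after resolution) and
#'   `mendel` (a [check_mendelian()] report).
#' @export
resolve_pedigree_cn <- function(ped, diploid_cn, A = c(1L, 4L, 5L, 6L),
                                max_component = 10L) {
  validate_pedigree(ped)
  if (is.data.frame(diploid_cn))
    diploid_cn <- stats::setNames(diploid_cn$diploid_cn, diploid_cn$id)
  d <- diploid_cn[ped$id]
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  cand <- .candidate_sets(d, sort(unique(as.integer(A))))
  names(cand) <- ped$id
  cand0 <- cand   # depth-implied sets, kept for the Mendelian report

  kids <- lapply(seq_len(n), function(i)
    which((!is.na(ped$sire) & ped$sire == ped$id[i]) |
            (!is.na(ped$dam) & ped$dam == ped$id[i])))

  filter_child <- function(i) {
    s <- ped$sire[i]; dm <- ped$dam[i]
    if (is.na(s) && is.na(dm)) return(FALSE)
    cs <- if (is.na(s)) NULL else cand[[idx[s]]]
    cd <- if (is.na(dm)) NULL else cand[[idx[dm]]]
    ci <- cand[[i]]
    if (nrow(ci) == 0) return(FALSE)
    keep <- vapply(seq_len(nrow(ci)), function(r) {
      ch <- ci[r, ]
      ok_s <- is.null(cs) || any(vapply(seq_len(nrow(cs)), function(q)
        ch[1] %in% cs[q, ] || ch[2] %in% cs[q, ], TRUE))
      if (!ok_s) return(FALSE)
      # joint check against both parents when both known
      if (!is.null(cs) && !is.null(cd)) {
        for (q1 in seq_len(nrow(cs))) for (q2 in seq_len(nrow(cd)))
          if (.pair_compatible(ch, cs[q1, ], cd[q2, ])) return(TRUE)
        return(FALSE)
      }
      if (!is.null(cd)) {
        return(any(vapply(seq_len(nrow(cd)), function(q)
          ch[1] %in% cd[q, ] || ch[2] %in% cd[q, ], TRUE)))
      }
      TRUE
    }, TRUE)
    changed <- !all(keep)
    cand[[i]] <<- ci[keep, , drop = FALSE]
    changed
  }

  filter_parent <- function(i) {
    if (length(kids[[i]]) == 0) return(FALSE)
    ci <- cand[[i]]
    if (nrow(ci) == 0) return(FALSE)
    keep <- vapply(seq_len(nrow(ci)), function(r) {
      p <- ci[r, ]
      for (k in kids[[i]]) {
        other <- if (!is.na(ped$sire[k]) && idx[ped$sire[k]] == i)
          ped$dam[k] else ped$sire[k]
        co <- if (is.na(other)) NULL else cand[[idx[other]]]
        ck <- cand[[k]]
        if (nrow(ck) == 0) next
        ok <- FALSE
        for (rk in seq_len(nrow(ck))) {
          ch <- ck[rk, ]
          if (is.null(co)) {
            if (ch[1] %in% p || ch[2] %in% p) { ok <- TRUE; break }
          } else {
            for (ro in seq_len(nrow(co)))
              if (.pair_compatible(ch, p, co[ro, ])) { ok <- TRUE; break }
            if (ok) break
          }
        }
        if (!ok) return(FALSE)
      }
      TRUE
    }, TRUE)
    changed <- !all(keep)
    cand[[i]] <<- ci[keep, , drop = FALSE]
    changed
  }

  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (filter_child(i)) changed <- TRUE
      if (filter_parent(i)) changed <- TRUE
    }
    if (!changed) break
  }

  ## exhaustive joint enumeration within small family components
  comp <- family_components(ped)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) < 2 || length(members) > max_component) next
    sizes <- vapply(members, function(i) max(1L, nrow(cand[[i]])), 1L)
    if (prod(sizes) > 2e5) next
    trios_cc <- intersect(members,
                          which(!is.na(ped$sire) | !is.na(ped$dam)))
    grid_idx <- lapply(members, function(i) seq_len(max(1L, nrow(cand[[i]]))))
    combos <- expand.grid(grid_idx)
    surv <- lapply(members, function(i) logical(nrow(cand[[i]])))
    names(surv) <- as.character(members)
    pos_in <- stats::setNames(seq_along(members), members)
    for (rr in seq_len(nrow(combos))) {
      assign_ok <- TRUE
      get_pair <- function(i) {
        ci <- cand[[i]]
        if (nrow(ci) == 0) return(NULL)
        ci[combos[rr, pos_in[as.character(i)]], ]
      }
      for (k in trios_cc) {
        ch <- get_pair(k)
        if (is.null(ch)) next
        s <- ped$sire[k]; dm <- ped$dam[k]
        ps <- if (is.na(s)) NULL else get_pair(idx[s])
        pd <- if (is.na(dm)) NULL else get_pair(idx[dm])
        ok <- if (!is.null(ps) && !is.null(pd)) .pair_compatible(ch, ps, pd)
        else if (!is.null(ps)) (ch[1] %in% ps || ch[2] %in% ps)
        else if (!is.null(pd)) (ch[1] %in% pd || ch[2] %in% pd)
        else TRUE
        if (!ok) { assign_ok <- FALSE; break }
      }
      if (assign_ok)
        for (i in members)
          if (nrow(cand[[i]]) > 0)
            surv[[as.character(i)]][combos[rr, pos_in[as.character(i)]]] <- TRUE
    }
    if (any(unlist(surv)))   # keep only candidates in some consistent config
      for (i in members)
        if (nrow(cand[[i]]) > 0)
          cand[[i]] <- cand[[i]][surv[[as.character(i)]], , drop = FALSE]
  }

  geno <- data.frame(
    id = ped$id,
    diploid_cn = as.integer(d),
    n_candidates = vapply(cand, nrow, 1L),
    stringsAsFactors = FALSE)
  geno$resolved <- geno$n_candidates == 1L
  geno$allele1 <- ifelse(geno$resolved,
                         vapply(cand, function(p)
                           if (nrow(p) == 1) p[1, 1] else NA_integer_, 1L),
                         NA_integer_)
  geno$allele2 <- ifelse(geno$resolved,
                         vapply(cand, function(p)
                           if (nrow(p) == 1) p[1, 2] else NA_integer_, 1L),
                         NA_integer_)
  geno$mul_dosage <- ifelse(geno$resolved,
                            (geno$allele1 > 1) + (geno$allele2 > 1),
                            NA_integer_)
  res <- structure(list(genotypes = geno, candidates = cand,
                        pedigree = ped),
                   class = "cn_genotypes")
  # Mendelian verdicts are judged against the depth-implied candidates:
  # a trio is incompatible iff no joint choice of those satisfies
  # transmission, regardless of what propagation later eliminated
  res$mendel <- check_mendelian(ped, cand0)
  res
}

#' @export
print.cn_genotypes <- function(x, ...) {
  g <- x$genotypes
  cat(sprintf("CNV genotypes: %d individuals, %d resolved, %d unresolved, %d empty\n",
              nrow(g), sum(g$n_candidates == 1), sum(g$n_candidates > 1),
              sum(g$n_candidates == 0)))
  print(x$mendel)
  invisible(x)
}

# Connected family components (links between child and each parent).
family_components <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  union2 <- function(i, j) comp[find(i)] <<- find(j)
  for (i in seq_len(n)) {
    if (!is.na(ped$sire[i])) union2(i, idx[ped$sire[i]])
    if (!is.na(ped$dam[i])) union2(i, idx[ped$dam[i]])
  }
  vapply(seq_len(n), find, 1L)
}

#' Check Mendelian consistency of CNV genotypes in trios/duos
#'
#' For every individual with at least one genotyped parent, verdicts:
#' `consistent` if the (resolved or candidate) pairs admit a transmission,
#' `incompatible` if no joint choice of candidate pairs satisfies
#' transmission, `undetermined` if candidate sets are empty/missing.
#'
#' @param ped pedigree.
#' @param genotypes a `cn_genotypes` object (or its `candidates` list).
#' @return object of class `mendel_report`: `data.frame` `trios` with
#'   columns `id`, `sire`, `dam`, `status`, plus totals in attributes.
#' @export
check_mendelian <- function(ped, genotypes) {
  cand <- if (inherits(genotypes, "cn_genotypes")) genotypes$candidates
  else genotypes
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  rows <- which(!is.na(ped$sire) | !is.na(ped$dam))
  status <- character(length(rows))
  for (r in seq_along(rows)) {
    k <- rows[r]
    ck <- cand[[k]]
    cs <- if (is.na(ped$sire[k])) NULL else cand[[idx[ped$sire[k]]]]
    cd <- if (is.na(ped$dam[k])) NULL else cand[[idx[ped$dam[k]]]]
    if (is.null(ck) || nrow(ck) == 0 ||
        (!is.null(cs) && nrow(cs) == 0) || (!is.null(cd) && nrow(cd) == 0)) {
      status[r] <- "undetermined"
      next
    }
    ok <- FALSE
    for (rk in seq_len(nrow(ck))) {
      ch <- ck[rk, ]
      if (!is.null(cs) && !is.null(cd)) {
        for (q1 in seq_len(nrow(cs))) for (q2 in seq_len(nrow(cd)))
          if (.pair_compatible(ch, cs[q1, ], cd[q2, ])) { ok <- TRUE; break }
      } else if (!is.null(cs)) {
        if (any(vapply(seq_len(nrow(cs)), function(q)
          ch[1] %in% cs[q, ] || ch[2] %in% cs[q, ], TRUE))) ok <- TRUE
      } else if (!is.null(cd)) {
        if (any(vapply(seq_len(nrow(cd)), function(q)
          ch[1] %in% cd[q, ] || ch[2] %in% cd[q, ], TRUE))) ok <- TRUE
      }
      if (ok) break
    }
    status[r] <- if (ok) "consistent" else "incompatible"
  }
  trios <- data.frame(id = ped$id[rows], sire = ped$sire[rows],
                      dam = ped$dam[rows], status = status,
                      stringsAsFactors = FALSE)
  structure(list(trios = trios,
                 n_consistent = sum(status == "consistent"),
                 n_incompatible = sum(status == "incompatible"),
                 n_undetermined = sum(status == "undetermined")),
            class = "mendel_report")
}

#' @export
print.mendel_report <- function(x, ...) {
  cat(sprintf("Mendelian check: %d consistent, %d incompatible, %d undetermined\n",
              x$n_consistent, x$n_incompatible, x$n_undetermined))
  invisible(x)
}

#' Correct allelic-imbalance genotype errors inside a CNV
#'
#' At a heterozygous site inside a multi-copy CNV the alternative-allele
#' read fraction is not 1/2 but `c / (a + b)` (alt allele on the haplotype
#' with copy number `c`, total copies `a + b`), so naive callers miscall
#' strongly imbalanced Ref/Alt genotypes as Alt/Alt. For every intra-CNV
#' site this routine re-evaluates each individual's call by binomial
#' likelihood over the genotype hypotheses implied by its resolved CN pair
#' (hom-ref: alt fraction `eps`; het with alt on either haplotype:
#' `a/(a+b)` or `b/(a+b)`; hom-alt: `1 - eps`) and logs every change with
#' its evidence. Corrections that would create a new trio Mendelian error
#' at that site are reverted.
#'
#' @param counts a `site_read_counts` object (matrices `ref`, `alt`).
#' @param genotypes integer matrix of called diploid genotypes
#'   (individuals x sites; 0/1/2 alt-allele dosage, NA missing).
#' @param cn_genotypes a `cn_genotypes` object from
#'   [resolve_pedigree_cn()].
#' @param ped pedigree (for the trio guard); `NULL` skips it.
#' @param cnv_sites indices (columns) of sites inside the CNV interval;
#'   defaults to sites with positions within the CNV interval recorded in
#'   `counts` if available.
#' @param eps sequencing-error rate for the homozygous hypotheses.
#' @return list with `genotypes` (corrected matrix) and `corrections`
#'   (`data.frame`: id, site, before, after, ref_depth, alt_depth,
#'   expected_alt_fraction).
#' @export
correct_imbalanced_genotypes <- function(counts, genotypes, cn_genotypes,
                                         ped = NULL, cnv_sites = NULL,
                                         eps = 0.01) {
  g <- cn_genotypes$genotypes
  if (is.null(cnv_sites)) stop("cnv_sites (intra-CNV column indices) required")
  ids <- rownames(genotypes)
  corrected <- genotypes
  logs <- list()
  skipped <- 0L
  for (s in cnv_sites) {
    for (i in seq_along(ids)) {
      gi <- g[g$id == ids[i], ]
      if (nrow(gi) == 0 || !isTRUE(gi$resolved)) {
        skipped <- skipped + 1L
        next   # missing CN genotype: leave unchanged
      }
      a <- gi$allele1; b <- gi$allele2
      tot <- a + b
      hyp_p <- c(hom_ref = eps,
                 het_1 = a / tot, het_2 = b / tot,
                 hom_alt = 1 - eps)
      hyp_p <- hyp_p * (1 - eps) + (1 - hyp_p) * eps
      hyp_g <- c(0L, 1L, 1L, 2L)
      r <- counts$ref[i, s]; al <- counts$alt[i, s]
      if (r + al == 0) next
      ll <- stats::dbinom(al, r + al, hyp_p, log = TRUE)
      best <- which.max(ll)
      new_g <- hyp_g[best]
      old_g <- genotypes[i, s]
      if (!is.na(old_g) && new_g != old_g) {
        corrected[i, s] <- new_g
        logs[[length(logs) + 1L]] <- data.frame(
          id = ids[i], site = s, before = old_g, after = new_g,
          ref_depth = r, alt_depth = al,
          expected_alt_fraction = hyp_p[best],
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(ped)) {   # revert changes that add a Mendelian error
      trio_rows <- which(!is.na(ped$sire) & !is.na(ped$dam))
      for (k in trio_rows) {
        fam <- c(ped$id[k], ped$sire[k], ped$dam[k])
        if (!all(fam %in% ids)) next
        before_err <- .gt_trio_error(genotypes[fam[1], s],
                                     genotypes[fam[2], s],
                                     genotypes[fam[3], s])
        after_err <- .gt_trio_error(corrected[fam[1], s],
                                    corrected[fam[2], s],
                                    corrected[fam[3], s])
        if (after_err > before_err) {
          for (f in fam) corrected[f, s] <- genotypes[f, s]
          logs <- Filter(function(l) !(l$site == s && l$id %in% fam), logs)
        }
      }
    }
  }
  if (skipped > 0)
    warning(skipped, " individual-site call(s) left unchanged ",
            "(missing or unresolved CN genotype)")
  corrections <- if (length(logs)) do.call(rbind, logs)
  else data.frame(id = character(), site = integer(), before = integer(),
                  after = integer(), ref_depth = integer(),
                  alt_depth = integer(), expected_alt_fraction = numeric())
  list(genotypes = corrected, corrections = corrections)
}

# 1 if a biallelic trio genotype configuration is Mendelian-impossible.
.gt_trio_error <- function(child, sire, dam) {
  if (anyNA(c(child, sire, dam))) return(0L)
  poss_s <- unique(c(floor(sire / 2), ceiling(sire / 2)))
  poss_d <- unique(c(floor(dam / 2), ceiling(dam / 2)))
  ok <- any(outer(poss_s, poss_d, "+") == child)
  if (ok) 0L else 1L
}

#' Discover tag SNPs for the biallelically coded CNV
#'
#' Computes r-squared (squared Pearson correlation) between the CNV's Mul
#' dosage and every SNP's diploid dosage, returning sites at or above the
#' threshold sorted by r-squared (descending) then position (ascending),
#' with a flag for sites inside the CNV interval. Zero-variance sites are
#' skipped with a warning.
#'
#' @param dosages integer matrix (individuals x sites) of SNP dosages.
#' @param wt_mul_dosage numeric vector of per-individual Mul dosages.
#' @param positions site positions (bp).
#' @param cnv_interval length-2 interval for the `in_cnv` flag.
#' @param r2_threshold minimum r-squared (default 0.98).
#' @return `data.frame`: `site`, `position`, `r2`, `in_cnv`.
#' @export
find_tag_snps <- function(dosages, wt_mul_dosage, positions,
                          cnv_interval = NULL, r2_threshold = 0.98) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1)
  if (stats::var(wt_mul_dosage) == 0)
    stop("CNV dosage has zero variance; r2 undefined")
  v <- apply(dosages, 2, stats::var)
  if (any(v == 0))
    warning(sum(v == 0), " zero-variance site(s) skipped")
  r2 <- rep(NA_real_, ncol(dosages))
  r2[v > 0] <- drop(stats::cor(wt_mul_dosage,
                               dosages[, v > 0, drop = FALSE]))^2
  keep <- which(!is.na(r2) & r2 >= r2_threshold)
  out <- data.frame(site = keep, position = positions[keep],
                    r2 = r2[keep],
                    in_cnv = if (is.null(cnv_interval)) NA
                    else positions[keep] >= cnv_interval[1] &
                      positions[keep] <= cnv_interval[2])
  out[order(-out$r2, out$position), , drop = FALSE]
}
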