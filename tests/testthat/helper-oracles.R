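# Independent oracles and shared fixtures for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pedigree CN resolver: enumerate every joint assignment of
# candidate pairs across the family and keep, per individual, the
# candidates occurring in at least one transmission-consistent assignment.
# Deliberately naive (full cartesian product) and independent of the
# constraint-propagation implementation it checks.
brute_force_resolve <- function(ped, diploid_cn, A = c(1L, 4L, 5L, 6L)) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  cand <- lapply(diploid_cn[ped$id], function(d) {
    if (is.na(d)) {
      ap <- expand.grid(a = A, b = A)
      as.matrix(ap[ap$a <= ap$b, , drop = FALSE])
    } else enumerate_allele_pairs(d, A)
  })
  sizes <- vapply(cand, function(p) max(1L, nrow(p)), 1L)
  combos <- expand.grid(lapply(sizes, seq_len))
  ok_pair <- function(ch, p1, p2) {
    (ch[1] %in% p1 && ch[2] %in% p2) || (ch[2] %in% p1 && ch[1] %in% p2)
  }
  surv <- lapply(cand, function(p) logical(max(1L, nrow(p))))
  for (r in seq_len(nrow(combos))) {
    pairs <- lapply(seq_len(n), function(i) {
      if (nrow(cand[[i]]) == 0) NULL else cand[[i]][combos[r, i], ]
    })
    consistent <- TRUE
    for (k in seq_len(n)) {
      if (is.null(pairs[[k]])) next
      s <- ped$sire[k]; d <- ped$dam[k]
      ps <- if (is.na(s)) NULL else pairs[[idx[s]]]
      pd <- if (is.na(d)) NULL else pairs[[idx[d]]]
      ok <- if (!is.null(ps) && !is.null(pd)) ok_pair(pairs[[k]], ps, pd)
      else if (!is.null(ps)) any(pairs[[k]] %in% ps)
      else if (!is.null(pd)) any(pairs[[k]] %in% pd)
      else TRUE
      if (!ok) { consistent <- FALSE; break }
    }
    if (consistent)
      for (i in seq_len(n))
        if (nrow(cand[[i]]) > 0) surv[[i]][combos[r, i]] <- TRUE
  }
  satisfiable <- any(vapply(seq_len(n), function(i)
    nrow(cand[[i]]) == 0 || any(surv[[i]]), TRUE)) &&
    all(vapply(seq_len(n), function(i)
      nrow(cand[[i]]) == 0 || any(surv[[i]]), TRUE))
  out <- lapply(seq_len(n), function(i) {
    if (nrow(cand[[i]]) == 0) cand[[i]]
    else cand[[i]][surv[[i]], , drop = FALSE]
  })
  names(out) <- ped$id
  attr(out, "satisfiable") <- satisfiable
  out
}

# Naive EHH: explicit pairwise identity over the prefix of sites from the
# core to each position, per direction.
ehh_naive <- function(H, core, allele, direction = c("right", "left")) {
  direction <- match.arg(direction)
  carriers <- which(H[, core] == allele)
  nc <- length(carriers)
  site_seq <- if (direction == "right") core:ncol(H) else core:1
  vapply(seq_along(site_seq), function(k) {
    cols <- site_seq[seq_len(k)]
    same <- 0L
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc)
      if (all(H[carriers[i], cols] == H[carriers[j], cols]))
        same <- same + 1L
    same / choose(nc, 2)
  }, 0)
}

# Compact cohort configuration for fast unit tests.
test_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_individuals = 60, n_trios = 15, n_snps = 120, seed = 1)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Site-level biallelic trio inconsistency count (independent of the
# genotyper's internal check).
trio_gt_errors <- function(geno, ped, site) {
  trios <- which(!is.na(ped$sire) & !is.na(ped$dam))
  bad <- 0L
  for (k in trios) {
    ch <- geno[ped$id[k], site]
    s <- geno[ped$sire[k], site]
    d <- geno[ped$dam[k], site]
    if (anyNA(c(ch, s, d))) next
    from_s <- unique(c(floor(s / 2), ceiling(s / 2)))
    from_d <- unique(c(floor(d / 2), ceiling(d / 2)))
    if (!any(outer(from_s, from_d, "+") == ch)) bad <- bad + 1L
  }
  bad
}
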