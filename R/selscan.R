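#' Extended haplotype homozygosity around a core allele
#'
#' For the haplotypes carrying `core_allele` at `core_site`, EHH at a
#' position `x` is the probability that two randomly drawn carrier
#' haplotypes are identical at every site from the core out to `x`:
#' `EHH(x) = sum_h C(n_h, 2) / C(n_c, 2)` over the groups of haplotypes
#' still identical over the extension interval. Computed independently to
#' the left and right of the core; EHH equals 1 at the core and is
#' monotonically non-increasing outward.
#'
#' @param panel a `haplotype_panel` (or a bare 0/1 matrix with a
#'   `positions` attribute).
#' @param core_site column index of the core site.
#' @param core_allele allele (0 or 1) defining the carrier set.
#' @param min_haplotypes minimum carrier count (default 2; EHH is
#'   undefined for singleton cores).
#' @param stop_at stop extending once EHH falls below this level (the
#'   first sub-threshold value is kept so integrators can interpolate the
#'   crossing). Default 0 returns the full curve.
#' @return `data.frame` with columns `position`, `direction`
#'   (`"left"`/`"right"`), `ehh`. The core site appears in both directions
#'   with `ehh = 1`.
#' @export
compute_ehh <- function(panel, core_site, core_allele,
                        min_haplotypes = 2L, stop_at = 0) {
  H <- if (inherits(panel, "haplotype_panel")) panel$haplotypes else panel
  positions <- if (inherits(panel, "haplotype_panel")) panel$positions
  else attr(panel, "positions")
  carriers <- which(H[, core_site] == core_allele)
  nc <- length(carriers)
  if (nc < min_haplotypes)
    stop("EHH undefined: core allele carried by ", nc, " haplotype(s)")
  Hc <- H[carriers, , drop = FALSE]
  denom <- choose(nc, 2)
  one_side <- function(site_seq) {
    grp <- rep(1L, nc)
    ehh <- numeric(length(site_seq))
    last <- length(site_seq)
    for (k in seq_along(site_seq)) {
      s <- site_seq[k]
      key <- grp * 2L + Hc[, s]
      grp <- match(key, unique(key))
      sizes <- tabulate(grp)
      ehh[k] <- sum(choose(sizes, 2)) / denom
      if (ehh[k] == 0) {               # cannot recover; fill and stop
        last <- length(site_seq)
        if (k < last) ehh[(k + 1):last] <- 0
        break
      }
      if (ehh[k] < stop_at) { last <- k; break }
    }
    ehh[seq_len(last)]
  }
  m <- ncol(H)
  right_seq <- core_site:m
  left_seq <- core_site:1
  el <- one_side(left_seq)
  er <- one_side(right_seq)
  rbind(
    data.frame(position = positions[left_seq[seq_along(el)]],
               direction = "left", ehh = el),
    data.frame(position = positions[right_seq[seq_along(er)]],
               direction = "right", ehh = er)
  )
}

# Trapezoid integral of an EHH curve over physical distance, truncated
# (with linear interpolation) where EHH drops below `cutoff`.
.integrate_ehh <- function(pos, ehh, cutoff = 0.05) {
  stopifnot(length(pos) == length(ehh))
  if (length(pos) < 2) return(0)
  area <- 0
  for (k in seq_len(length(pos) - 1)) {
    x0 <- pos[k]; x1 <- pos[k + 1]
    e0 <- ehh[k]; e1 <- ehh[k + 1]
    if (e0 < cutoff) break
    if (e1 >= cutoff) {
      area <- area + abs(x1 - x0) * (e0 + e1) / 2
    } else {
      # interpolate the crossing point
      frac <- if (e0 == e1) 0 else (e0 - cutoff) / (e0 - e1)
      area <- area + abs(x1 - x0) * frac * (e0 + cutoff) / 2
      break
    }
  }
  area
}

#' Unstandardized integrated haplotype score at a core site
#'
#' Computes the EHH curves of the ancestral and derived alleles, integrates
#' each over physical position (trapezoid rule, truncated where EHH drops
#' below `cutoff`, default 0.05) into iHH_A and iHH_D, and returns
#' `iHS_u = ln(iHH_A / iHH_D)`. Under the usual sign convention a sweep on
#' the derived allele gives long derived haplotypes, hence negative iHS.
#'
#' @param panel a `haplotype_panel` with an `ancestral` annotation.
#' @param core_site column index.
#' @param cutoff EHH truncation level for the integration.
#' @param min_haplotypes minimum count of each allele (default 2).
#' @return one-row `data.frame`: `site`, `position`, `freq_derived`,
#'   `ihh_a`, `ihh_d`, `ihs_u` (`NA` with a flag when undefined).
#' @export
compute_ihs <- function(panel, core_site, cutoff = 0.05,
                        min_haplotypes = 2L) {
  anc <- panel$ancestral[core_site]
  der <- 1L - anc
  alle <- panel$haplotypes[, core_site]
  n_der <- sum(alle == der)
  n_anc <- sum(alle == anc)
  out <- data.frame(site = core_site,
                    position = panel$positions[core_site],
                    freq_derived = n_der / length(alle),
                    ihh_a = NA_real_, ihh_d = NA_real_,
                    ihs_u = NA_real_)
  if (n_der < min_haplotypes || n_anc < min_haplotypes) return(out)
  ihh <- function(allele) {
    e <- compute_ehh(panel, core_site, allele,
                     min_haplotypes = min_haplotypes, stop_at = cutoff)
    l <- e[e$direction == "left", ]
    r <- e[e$direction == "right", ]
    .integrate_ehh(l$position, l$ehh, cutoff) +
      .integrate_ehh(r$position, r$ehh, cutoff)
  }
  out$ihh_a <- ihh(anc)
  out$ihh_d <- ihh(der)
  if (out$ihh_d > 0 && out$ihh_a > 0)
    out$ihs_u <- log(out$ihh_a / out$ihh_d)
  out
}

#' iHS scan over all (or selected) sites of a panel
#'
#' @param panel a `haplotype_panel`.
#' @param sites column indices to scan (default: all sites with both
#'   alleles at count >= `min_haplotypes`).
#' @param min_maf minimum derived-allele frequency folded to MAF for
#'   inclusion (default 0.05).
#' @param cutoff EHH truncation level.
#' @param min_haplotypes per-allele minimum haplotype count.
#' @return `data.frame` of per-site [compute_ihs()] rows.
#' @export
ihs_scan <- function(panel, sites = NULL, min_maf = 0.05, cutoff = 0.05,
                     min_haplotypes = 2L) {
  freq <- colMeans(panel$haplotypes)
  if (is.null(sites))
    sites <- which(pmin(freq, 1 - freq) >= min_maf)
  do.call(rbind, lapply(sites, function(s)
    compute_ihs(panel, s, cutoff, min_haplotypes)))
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Within each of `n_bins` equal-width derived-allele-frequency bins,
#' subtracts the bin mean and divides by the bin standard deviation; the
#' standardized score is referred to a two-sided standard normal and
#' reported as -log10 p. Bins with fewer than 2 scores or zero variance
#' leave their sites flagged unstandardizable (`NA`).
#'
#' @param scan `data.frame` from [ihs_scan()] (columns `ihs_u`,
#'   `freq_derived`).
#' @param n_bins number of frequency bins (default 20).
#' @return the input with added columns `bin`, `ihs_std`, `mlog10p`.
#' @export
standardize_ihs <- function(scan, n_bins = 20L) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scan$freq_derived, breaks, include.lowest = TRUE,
             labels = FALSE)
  ihs_std <- rep(NA_real_, nrow(scan))
  for (b in unique(bin[!is.na(scan$ihs_u)])) {
    in_bin <- which(bin == b & !is.na(scan$ihs_u))
    if (length(in_bin) < 2) next
    mu <- mean(scan$ihs_u[in_bin])
    sdv <- stats::sd(scan$ihs_u[in_bin])
    if (sdv == 0) next                 # zero-variance bin: flagged NA
    ihs_std[in_bin] <- (scan$ihs_u[in_bin] - mu) / sdv
  }
  scan$bin <- bin
  scan$ihs_std <- ihs_std
  scan$mlog10p <- -(stats::pnorm(abs(ihs_std), lower.tail = FALSE,
                                 log.p = TRUE) + log(2)) / log(10)
  scan
}
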