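#' Median-of-ratios count normalization
#'
#' Size factors in the median-of-ratios family: for each sample, the
#' median over expressed genes of `count / geometric-row-mean`, rescaled so
#' the size factors have geometric mean 1. Genes with a zero count in any
#' sample are excluded from factor estimation (their geometric mean is not
#' finite on the log scale), but all genes are returned normalized.
#'
#' @param counts numeric matrix, features x samples.
#' @param rescale rescale the factors to geometric mean 1 (default); with
#'   `rescale = FALSE` the raw median ratios to the geometric-mean
#'   reference sample are returned (the DESeq-style convention). Under
#'   either convention, multiplying one sample's counts by `c` multiplies
#'   its factor by `c` relative to every other sample.
#' @return list with `size_factors` (named) and `normalized` (`counts`
#'   divided per-column by its size factor).
#' @export
normalize_counts <- function(counts, rescale = TRUE) {
  if (ncol(counts) < 2) stop("need at least 2 samples")
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no gene is expressed in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    r <- log(cnt) - log_gm[use]
    r <- r[is.finite(r)]
    if (!length(r)) stop("a sample shares no expressed genes with the reference")
    exp(stats::median(r))
  })
  if (rescale) sf <- sf / exp(mean(log(sf)))
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Remove principal-component outlier samples
#'
#' Projects samples on the top `n_pcs` principal components of the
#' (log-transformed, centred) normalized expression matrix and removes any
#' sample whose score deviates from the mean by more than `sd_cutoff`
#' standard deviations on any of those components. One pass only (no
#' refit-and-repeat loop).
#'
#' @param normalized matrix, features x samples.
#' @param n_pcs number of leading components to screen (default 4).
#' @param sd_cutoff deviation threshold in bin standard deviations
#'   (default 3.5).
#' @param log_transform apply `log2(x + 1)` before the PCA.
#' @return list with `retained` (sample names), `removed`, `scores`
#'   (sample x PC matrix).
#' @export
pc_outlier_filter <- function(normalized, n_pcs = 4L, sd_cutoff = 3.5,
                              log_transform = TRUE) {
  X <- if (log_transform) log2(normalized + 1) else normalized
  n_pcs <- min(n_pcs, ncol(X) - 1L, nrow(X))
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  dev <- abs(scale(scores))
  out <- apply(dev > sd_cutoff, 1, any)
  retained <- colnames(normalized)[!out]
  if (length(retained) < 3) stop("fewer than 3 samples remain after filtering")
  list(retained = retained, removed = colnames(normalized)[out],
       scores = scores)
}

#' Residualize expression on hidden factors (expression PCs)
#'
#' Regresses each feature on the top `K` principal components of the
#' expression matrix and returns the residuals (plus the grand mean per
#' feature, so the location is preserved). With `K = 0` the input is
#' returned unchanged. The residuals are exactly orthogonal to the removed
#' factors. This is the deterministic PCA surrogate for Bayesian
#' hidden-factor models commonly used before eQTL mapping.
#'
#' @param normalized matrix, features x samples.
#' @param K number of expression PCs to remove.
#' @param log_transform apply `log2(x + 1)` before factor estimation and
#'   residualization.
#' @param exclude_features optional feature names (rows) left out of the
#'   factor estimation (e.g. the focal cis region's genes, so a strong
#'   cis effect cannot leak into the factors); excluded features are
#'   still residualized.
#' @return list with `residualized` (features x samples) and `factors`
#'   (samples x K scores).
#' @export
residualize_hidden_factors <- function(normalized, K = 10L,
                                       log_transform = TRUE,
                                       exclude_features = NULL) {
  if (K >= ncol(normalized)) stop("K must be smaller than the sample count")
  X <- if (log_transform) log2(normalized + 1) else normalized
  if (K == 0)
    return(list(residualized = X, factors = NULL))
  Xf <- X
  if (!is.null(exclude_features))
    Xf <- X[setdiff(rownames(X), exclude_features), , drop = FALSE]
  pc <- stats::prcomp(t(Xf), center = TRUE, scale. = FALSE)
  Fk <- pc$x[, seq_len(K), drop = FALSE]
  # residualize each feature (rows) on the factor scores
  Xc <- X - rowMeans(X)
  B <- Xc %*% Fk %*% solve(crossprod(Fk))
  R <- Xc - B %*% t(Fk) + rowMeans(X)
  list(residualized = R, factors = Fk)
}

#' cis-eQTL scan for one gene or transcript
#'
#' Simple per-variant linear regression of a (residualized) expression
#' phenotype on variant dosage within a window around the feature, with a
#' two-sided t-test. Gene-level and transcript-level phenotypes are
#' handled identically. Monomorphic variants are skipped (flagged
#' untested).
#'
#' @param expression numeric vector (one feature across samples).
#' @param dosages matrix, samples x variants.
#' @param positions variant positions (bp).
#' @param feature_pos feature anchor position (bp); with `window`, limits
#'   the scan to `feature_pos +/- window`. `NULL` scans all variants.
#' @param window cis window half-width in bp (default 1e6).
#' @param covariates optional sample-level covariates, residualized out of
#'   both expression and dosage before the per-variant fit.
#' @return an `association_table` `data.frame` (`variant`, `position`,
#'   `freq`, `beta`, `se`, `mlog10p`, `tested`).
#' @export
cis_eqtl_scan <- function(expression, dosages, positions,
                          feature_pos = NULL, window = 1e6,
                          covariates = NULL) {
  if (length(expression) < 3) stop("need at least 3 samples")
  stopifnot(length(expression) == nrow(dosages))
  keep <- if (is.null(feature_pos)) rep(TRUE, ncol(dosages))
  else abs(positions - feature_pos) <= window
  G <- dosages[, keep, drop = FALSE]
  pos <- positions[keep]
  y <- expression
  p_cov <- 1L
  if (!is.null(covariates)) {
    Xc <- cbind(1, covariates)
    Q <- qr(Xc)
    y <- qr.resid(Q, y)
    G <- qr.resid(Q, G)
    p_cov <- ncol(Xc)
  } else {
    y <- y - mean(y)
    G <- sweep(G, 2, colMeans(G))
  }
  n <- length(y)
  gg <- colSums(G^2)
  tested <- gg > 1e-12
  beta <- ifelse(tested, colSums(G * y) / gg, NA_real_)
  df <- n - p_cov - 1L
  rss <- pmax(sum(y^2) - beta^2 * gg, 0)
  se <- sqrt(rss / df / gg)
  tval <- beta / se
  mlog10p <- -(stats::pt(abs(tval), df, lower.tail = FALSE,
                         log.p = TRUE) + log(2)) / log(10)
  Vn <- colnames(dosages)[keep]
  if (is.null(Vn)) Vn <- paste0("v", which(keep))
  out <- data.frame(variant = Vn, position = pos,
                    freq = colMeans(dosages[, keep, drop = FALSE]) / 2,
                    beta = beta, se = se,
                    mlog10p = ifelse(tested, mlog10p, NA_real_),
                    tested = tested, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}

#' SMR and HEIDI causal-gene test from summary statistics
#'
#' Summary-data-based Mendelian randomization: at the top cis-eQTL variant
#' (the instrument), the effect of expression on the trait is
#' `b_xy = b_GWAS / b_eQTL`, tested with
#' `T_SMR = z_G^2 z_E^2 / (z_G^2 + z_E^2)` against chi-square(1). The
#' HEIDI heterogeneity test asks whether the per-SNP `b_xy` estimates at
#' up to `m_max` secondary cis-SNPs (eQTL p below `p_heidi_eqtl`, LD
#' r-squared to the instrument within `r2_range`) are consistent with a
#' single shared causal variant: differences `d_i = b_xy(i) - b_xy(top)`
#' are referred, with their LD-derived delta-method covariance, to
#' chi-square with `m - 1` degrees of freedom. A gene is flagged
#' prioritized iff `-log10 p_SMR > smr_mlog10p` and `p_HEIDI > heidi_p`.
#'
#' @param gwas,eqtl `association_table`s sharing variant ids (columns
#'   `variant`, `beta`, `se`).
#' @param ld signed LD correlation matrix of the shared variants
#'   (dimnames = variant ids), e.g. `cor()` of the dosage matrix.
#' @param gene label carried into the result.
#' @param p_instrument maximum eQTL p for the instrument (default 5e-8).
#' @param p_heidi_eqtl eQTL p cutoff for secondary HEIDI SNPs
#'   (default 1.57e-3).
#' @param r2_range LD r-squared window to the instrument for HEIDI SNPs.
#' @param m_max maximum number of HEIDI SNPs (default 20).
#' @param smr_mlog10p,heidi_p prioritization thresholds (defaults 5 and
#'   0.05).
#' @return object of class `smr_result` (one-row `data.frame`): `gene`,
#'   `top_snp`, `b_xy`, `t_smr`, `p_smr`, `mlog10p_smr`, `n_heidi`,
#'   `p_heidi`, `testable`, `prioritized`.
#' @export
smr_heidi <- function(gwas, eqtl, ld, gene = "gene",
                      p_instrument = 5e-8, p_heidi_eqtl = 1.57e-3,
                      r2_range = c(0.05, 0.9), m_max = 20L,
                      smr_mlog10p = 5, heidi_p = 0.05) {
  shared <- Reduce(intersect, list(gwas$variant, eqtl$variant,
                                   rownames(ld)))
  out <- data.frame(gene = gene, top_snp = NA_character_,
                    b_xy = NA_real_, t_smr = NA_real_, p_smr = NA_real_,
                    mlog10p_smr = NA_real_, n_heidi = 0L,
                    p_heidi = NA_real_, testable = FALSE,
                    prioritized = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("smr_result", "data.frame")
  if (length(shared) == 0) return(out)
  gw <- gwas[match(shared, gwas$variant), ]
  eq <- eqtl[match(shared, eqtl$variant), ]
  z_e <- eq$beta / eq$se
  z_g <- gw$beta / gw$se
  p_e <- 2 * stats::pnorm(-abs(z_e))
  ok <- is.finite(z_e) & is.finite(z_g)
  inst_ok <- ok & p_e <= p_instrument
  if (!any(inst_ok)) return(out)        # no valid instrument: untestable
  top <- which(inst_ok)[which.max(abs(z_e[inst_ok]))]
  out$testable <- TRUE
  out$top_snp <- shared[top]
  out$b_xy <- gw$beta[top] / eq$beta[top]
  t_smr <- (z_g[top]^2 * z_e[top]^2) / (z_g[top]^2 + z_e[top]^2)
  out$t_smr <- t_smr
  out$p_smr <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  out$mlog10p_smr <- -stats::pchisq(t_smr, df = 1, lower.tail = FALSE,
                                    log.p = TRUE) / log(10)

  ## HEIDI
  r_top <- ld[shared, shared[top]]
  r2 <- r_top^2
  sec <- which(ok & p_e <= p_heidi_eqtl & r2 >= r2_range[1] &
                 r2 <= r2_range[2] & seq_along(shared) != top)
  if (length(sec) > m_max)
    sec <- sec[order(p_e[sec])][seq_len(m_max)]
  if (length(sec) >= 2) {
    snps <- c(top, sec)
    bG <- gw$beta[snps]; sG <- gw$se[snps]
    bE <- eq$beta[snps]; sE <- eq$se[snps]
    R <- ld[shared[snps], shared[snps]]
    bxy <- bG / bE
    m <- length(snps)
    # delta-method covariance of the b_xy estimates under LD R
    cov_bxy <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      cov_bxy[i, j] <- R[i, j] * sG[i] * sG[j] / (bE[i] * bE[j]) +
        bxy[i] * bxy[j] * R[i, j] * sE[i] * sE[j] / (bE[i] * bE[j])
    }
    # differences to the instrument (index 1)
    k <- m - 1
    Dmat <- cbind(-1, diag(k))          # d = bxy[-1] - bxy[1]
    d <- bxy[-1] - bxy[1]
    V <- Dmat %*% cov_bxy %*% t(Dmat)
    T_h <- tryCatch(drop(t(d) %*% solve(V, d)), error = function(e) {
      Vi <- MASS::ginv(V)
      drop(t(d) %*% Vi %*% d)
    })
    out$n_heidi <- m
    out$p_heidi <- stats::pchisq(T_h, df = k, lower.tail = FALSE)
  }
  out$prioritized <- isTRUE(out$mlog10p_smr > smr_mlog10p) &&
    (is.na(out$p_heidi) || out$p_heidi > heidi_p)
  out
}

#' @export
print.smr_result <- function(x, ...) {
  if (!x$testable[1]) {
    cat(sprintf("SMR (%s): untestable (no valid instrument)\n", x$gene[1]))
    return(invisible(x))
  }
  cat(sprintf(
    "SMR (%s): instrument %s, b_xy = %.3f, -log10 p_SMR = %.2f, p_HEIDI = %s (%d SNPs) -> %s\n",
    x$gene[1], x$top_snp[1], x$b_xy[1], x$mlog10p_smr[1],
    ifelse(is.na(x$p_heidi[1]), "NA", sprintf("%.3f", x$p_heidi[1])),
    x$n_heidi[1],
    ifelse(x$prioritized[1], "prioritized", "not prioritized")))
  invisible(x)
}
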