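#' Genomic relationship matrix (VanRaden form)
#'
#' `G = Z Z' / (2 * sum(p * (1 - p)))` with `Z = dosage - 2p`, `p` the
#' observed alternative-allele frequencies of the background markers.
#' Monomorphic markers are excluded; markers overlapping an exclusion
#' region (e.g. the QTL window, to avoid absorbing the causal signal into
#' the polygenic term) can be removed.
#'
#' @param dosages numeric matrix (individuals x markers), 0/1/2 coding.
#' @param positions optional marker positions (bp), needed for `exclude`.
#' @param exclude optional length-2 interval of positions to drop.
#' @return object of class `grm`: list with `G` (n x n), `freq`,
#'   `n_markers`.
#' @export
compute_grm <- function(dosages, positions = NULL, exclude = NULL) {
  if (nrow(dosages) < 2) stop("need at least 2 individuals")
  keep <- rep(TRUE, ncol(dosages))
  if (!is.null(exclude)) {
    if (is.null(positions)) stop("positions required when exclude is given")
    keep <- positions < exclude[1] | positions > exclude[2]
  }
  M <- dosages[, keep, drop = FALSE]
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1 & apply(M, 2, stats::var) > 0
  if (!any(poly)) stop("all markers monomorphic; GRM undefined")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  structure(list(G = G, freq = p, n_markers = sum(poly)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d individuals from %d markers; mean diagonal %.3f\n",
              nrow(x$G), x$n_markers, mean(diag(x$G))))
  invisible(x)
}

#' REML fit of the null linear mixed model y = Xb + g + e
#'
#' Variance components for `y ~ N(Xb, sigma_g2 * G + sigma_e2 * I)` are
#' estimated by restricted maximum likelihood using a single
#' eigendecomposition of `G` and one-dimensional optimization of the
#' profiled REML criterion over the log variance ratio
#' `log10(sigma_g2 / sigma_e2)` on `[-10, 10]` (tolerance 1e-6). The
#' rotated data and weights are cached for reuse in the per-SNP scan.
#'
#' @param y numeric phenotype vector.
#' @param grm a `grm` object (or bare matrix).
#' @param covariates optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @return object of class `cnv_lmm`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `loglik` (REML, up to a constant), plus cached rotation.
#' @export
fit_null_lmm <- function(y, grm, covariates = NULL) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (anyNA(y)) stop("y must be complete for analyzed individuals")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("G is not positive semi-definite beyond bending tolerance")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  p <- ncol(X)

  reml_ll <- function(log10_ratio) {
    lambda <- 10^log10_ratio            # sigma_g2 / sigma_e2
    v <- lambda * d + 1                 # V = sigma_e2 * diag(v)
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    r <- ys - drop(Xs %*% beta)
    rss <- sum(w * r^2)
    sigma_e2 <- rss / (n - p)
    -0.5 * ((n - p) * log(sigma_e2) + sum(log(v)) +
              determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(reml_ll, c(-10, 10), maximum = TRUE, tol = 1e-6)
  # compare against the boundary sigma_g2 = 0 (OLS)
  ll0 <- {
    XtX <- crossprod(Xs)
    beta <- solve(XtX, crossprod(Xs, ys))
    rss <- sum((ys - drop(Xs %*% beta))^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(s2) +
              determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  }
  if (ll0 >= opt$objective) {
    lambda <- 0; ll <- ll0
  } else {
    lambda <- 10^opt$maximum; ll <- opt$objective
  }
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  rss <- sum(w * (ys - drop(Xs %*% beta))^2)
  sigma_e2 <- rss / (n - p)
  sigma_g2 <- lambda * sigma_e2
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2),
                 loglik = as.numeric(ll),
                 lambda = lambda, U = U, d = d, w = w,
                 ys = ys, Xs = Xs, X = X, y = y),
            class = "cnv_lmm")
}

#' @export
print.cnv_lmm <- function(x, ...) {
  cat(sprintf("LMM variance components (REML): sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' Mixed-model association scan (EMMAX-style single-fit GLS)
#'
#' Tests each variant by generalized least squares with the variance
#' components fixed at the null-model fit: in the rotated space the model
#' is weighted least squares with weights `1 / (lambda * d + 1)`. Each
#' variant's effect, standard error and two-sided Wald p-value (t
#' reference, residual scale re-estimated per variant so the scan reduces
#' exactly to OLS when `sigma_g2 = 0`) are reported as -log10 p.
#' Conditioning SNPs enter the fixed effects. Set `exact = TRUE` to refit
#' the variance components for every variant (slower, exact per-SNP REML).
#'
#' @param fit a `cnv_lmm` from [fit_null_lmm()].
#' @param variants numeric matrix (individuals x variants) of dosages.
#' @param positions optional positions (bp) carried into the result.
#' @param conditional indices or names of columns of `variants` to add as
#'   fixed covariates.
#' @param exact refit variance components per variant.
#' @return `data.frame` of class `association_table`: `variant`,
#'   `position`, `freq`, `beta`, `se`, `mlog10p`; collinear variants keep
#'   `NA` with `tested = FALSE`.
#' @export
mixed_model_scan <- function(fit, variants, positions = NULL,
                             conditional = NULL, exact = FALSE) {
  stopifnot(inherits(fit, "cnv_lmm"))
  Vn <- colnames(variants)
  if (is.null(Vn)) Vn <- paste0("v", seq_len(ncol(variants)))
  cond_idx <- if (is.null(conditional)) integer(0)
  else if (is.character(conditional)) match(conditional, Vn)
  else as.integer(conditional)
  Xc <- fit$X
  if (length(cond_idx))
    Xc <- cbind(Xc, variants[, cond_idx, drop = FALSE])

  if (exact) {
    # per-variant REML refit: rebuild G once, refit with the variant in X,
    # then score that variant with its own variance components
    G <- fit$U %*% (fit$d * t(fit$U))
    rows <- lapply(seq_len(ncol(variants)), function(j) {
      fj <- tryCatch(
        fit_null_lmm(fit$y, G,
                     covariates = cbind(Xc[, -1, drop = FALSE],
                                        variants[, j, drop = FALSE])),
        error = function(e) NULL)
      if (is.null(fj)) return(NULL)
      mixed_model_scan(structure(modifyList(unclass(fj),
                                            list(X = Xc, Xs = crossprod(fj$U, Xc))),
                                 class = "cnv_lmm"),
                       variants[, j, drop = FALSE],
                       positions = if (is.null(positions)) NULL else positions[j])
    })
    out <- do.call(rbind, rows)
    out$variant <- Vn[!vapply(rows, is.null, TRUE)]
    class(out) <- c("association_table", "data.frame")
    return(out)
  }

  U <- fit$U
  w <- if (fit$lambda == 0) rep(1, length(fit$d)) else 1 / (fit$lambda * fit$d + 1)
  ys <- fit$ys
  Xs <- crossprod(U, Xc)
  Gs <- crossprod(U, variants)
  p0 <- ncol(Xs)
  n <- length(ys)
  # residualize y and each variant on the covariates under W
  XtWX <- crossprod(Xs, Xs * w)
  XtWXinv <- solve(XtWX)
  py <- ys - Xs %*% (XtWXinv %*% crossprod(Xs, ys * w))
  PG <- Gs - Xs %*% (XtWXinv %*% crossprod(Xs, Gs * w))
  gg <- colSums(w * PG^2)
  gy <- colSums(w * PG * drop(py))
  yy <- sum(w * drop(py)^2)
  tol <- 1e-10 * max(gg, 1)
  tested <- gg > tol
  beta <- ifelse(tested, gy / gg, NA_real_)
  df <- n - p0 - 1
  s2 <- pmax(yy - beta^2 * gg, 0) / df
  se <- sqrt(s2 / gg)
  tval <- beta / se
  mlog10p <- -(stats::pt(abs(tval), df, lower.tail = FALSE,
                         log.p = TRUE) + log(2)) / log(10)
  freq <- colMeans(variants) / 2
  out <- data.frame(variant = Vn,
                    position = if (is.null(positions)) NA_real_ else positions,
                    freq = freq, beta = beta, se = se,
                    mlog10p = ifelse(tested, mlog10p, NA_real_),
                    tested = tested,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha nominal significance level in (0, 1), default 0.01.
#' @return `-log10(alpha / n_tests)`.
#' @examples
#' bonferroni_threshold(28669, 0.01)   # 6.457...
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.01) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  -log10(alpha / n_tests)
}

#' Minor-allele-frequency filter
#'
#' Removes variants whose minor allele frequency is strictly below the
#' threshold (a variant at exactly the threshold is retained).
#'
#' @param freq numeric vector of alternative-allele frequencies.
#' @param threshold MAF threshold in [0, 0.5], default 0.025.
#' @return logical vector, `TRUE` = retained; the number removed is
#'   reported via a message.
#' @export
maf_filter <- function(freq, threshold = 0.025) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= threshold
  message(sum(!keep), " variant(s) removed at MAF < ", threshold)
  keep
}

#' Cross-trait colocalization by p-value correlation
#'
#' Rank (Spearman, default) or Pearson correlation between the -log10
#' p-values of two association tables over their shared variants, the
#' descriptive colocalization measure used for locus-compare plots.
#'
#' @param table_a,table_b `association_table`s (need columns `variant`,
#'   `mlog10p`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `rho`, `method`, `n_shared`, and `data` (paired
#'   -log10 p for plotting).
#' @export
coloc_correlation <- function(table_a, table_b, method = c("spearman",
                                                           "pearson")) {
  method <- match.arg(method)
  shared <- intersect(table_a$variant, table_b$variant)
  if (length(shared) < 3) stop("need at least 3 shared variants")
  a <- table_a$mlog10p[match(shared, table_a$variant)]
  b <- table_b$mlog10p[match(shared, table_b$variant)]
  ok <- is.finite(a) & is.finite(b)
  rho <- stats::cor(a[ok], b[ok], method = method)
  list(rho = rho, method = method, n_shared = sum(ok),
       data = data.frame(variant = shared[ok], mlog10p_a = a[ok],
                         mlog10p_b = b[ok]))
}
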