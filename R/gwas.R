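#' Single-SNP linear mixed model association scan
#'
#' Tests each marker for association with the phenotype under the LMM
#' y = X beta + s b + u + e with u ~ N(0, sigma2_g K). The default `"p3d"`
#' method estimates the variance components once under the null model
#' (P3D/EMMAX) and performs a generalized-least-squares Wald t-test per SNP
#' in the whitened basis; `"exact"` re-estimates the variance ratio by REML
#' for every SNP (slow, used as the reference implementation). Missing
#' genotypes are mean-imputed per marker. SNPs collinear with the
#' covariates are flagged and assigned p = 1.
#'
#' @param geno Dosage matrix (individuals x markers).
#' @param y Phenotype vector (one value per row of `geno`).
#' @param X Fixed-effect design; default intercept + 3 genotype principal
#'   components.
#' @param K Kinship matrix; default [compute_kinship()] of `geno`.
#' @param map Optional marker map supplying `chrom`/`pos` for the output.
#' @param method `"p3d"` (default) or `"exact"`.
#' @param fdr_q Benjamini-Hochberg FDR level for the significance flags.
#' @return Data frame of class `gwas_result`: `marker`, `chrom`, `pos`,
#'   `beta`, `se`, `p`, `neglog10p`, `fdr_sig`, `collinear`.
#' @export
single_snp_gwas <- function(geno, y, X = NULL, K = NULL, map = NULL,
                            method = c("p3d", "exact"), fdr_q = 0.05) {
  method <- match.arg(method)
  n <- nrow(geno)
  stopifnot(length(y) == n)
  if (is.null(K)) K <- compute_kinship(geno)
  if (is.null(X)) X <- cbind(Intercept = 1, genotype_pcs(geno, k = min(3L, n - 2L)))
  null <- fit_null_lmm(y, X, K)
  p_cov <- ncol(X)
  df <- n - p_cov - 1L

  Gi <- mean_impute(geno)
  sw <- sqrt(null$lambda * null$d + 1)
  Xw <- null$X_rot / sw
  yw <- null$y_rot / sw
  Q <- qr(Xw)
  yres <- qr.resid(Q, yw)

  m <- ncol(geno)
  beta <- se <- pval <- rep(NA_real_, m)
  collinear <- rep(FALSE, m)

  if (method == "p3d") {
    Gw <- crossprod(null$U, Gi) / sw
    Gr <- qr.resid(Q, Gw)
    sts <- colSums(Gr^2)
    sty <- as.numeric(crossprod(Gr, yres))
    tol <- 1e-8 * n
    ok <- sts > tol
    collinear <- !ok
    beta[ok] <- sty[ok] / sts[ok]
    rss <- pmax(sum(yres^2) - sty[ok]^2 / sts[ok], 1e-300)
    sigma2 <- rss / df
    se[ok] <- sqrt(sigma2 / sts[ok])
    tstat <- beta[ok] / se[ok]
    pval[ok] <- 2 * stats::pt(-abs(tstat), df)
    pval[!ok] <- 1
  } else {
    for (j in seq_len(m)) {
      s <- Gi[, j]
      Xs <- cbind(X, s)
      if (qr(Xs)$rank <= p_cov) {
        collinear[j] <- TRUE; pval[j] <- 1; next
      }
      fit <- reml_refit(y, Xs, null)
      beta[j] <- fit$beta[p_cov + 1L]
      se[j] <- fit$se[p_cov + 1L]
      pval[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), df)
    }
  }

  res <- data.frame(
    marker = colnames(geno) %||% paste0("M", seq_len(m)),
    chrom = if (!is.null(map)) map$chrom else NA_integer_,
    pos = if (!is.null(map)) map$pos else NA_integer_,
    beta = beta, se = se, p = pval,
    neglog10p = -log10(pmax(pval, 1e-300)),
    collinear = collinear,
    stringsAsFactors = FALSE
  )
  res$fdr_sig <- bh_fdr(res$p, q = fdr_q)$significant
  class(res) <- c("gwas_result", "data.frame")
  res
}

# exact per-SNP REML refit reusing the null fit's spectral cache
#' @keywords internal
#' @noRd
reml_refit <- function(y, Xs, null) {
  Xr <- crossprod(null$U, Xs)
  ldet_xx <- determinant(crossprod(Xs), logarithm = TRUE)$modulus
  obj <- function(ll) -reml_ll_1k(exp(ll), null$y_rot, Xr, null$d, ldet_xx)$ll
  grid <- seq(-10, 10, length.out = 21)
  i0 <- which.min(vapply(grid, obj, numeric(1)))
  opt <- stats::optimize(obj, c(grid[max(1L, i0 - 1L)], grid[min(21L, i0 + 1L)]))
  lam <- exp(opt$minimum)
  fit <- reml_ll_1k(lam, null$y_rot, Xr, null$d, ldet_xx)
  w <- lam * null$d + 1
  Xw <- Xr / sqrt(w)
  covb <- fit$sigma2 * solve(crossprod(Xw))
  list(beta = fit$beta, se = sqrt(diag(covb)), lambda = lam)
}

#' Sliding-window SNP-set kernel association scan
#'
#' Tests windows of consecutive SNPs jointly through a window-specific
#' random effect whose covariance is the linear kernel of the window's
#' standardized genotypes, on top of the genome-wide kinship null model
#' (variance components fixed at their null REML estimates). For each focal
#' SNP the window spans `focal - window_half` to `focal + window_half`,
#' truncated at chromosome ends; the p-value is assigned to the focal SNP.
#'
#' Two tests are available. The default `"score"` is the variance-component
#' score test: the quadratic statistic is referred to its exact
#' weighted-chi-square null distribution (Imhof integration, with a
#' Liu-type moment-matched fallback), giving continuous, null-uniform
#' p-values. `"lrt"` is the restricted likelihood-ratio test against the
#' 0.5 chi2_0 + 0.5 chi2_1 boundary mixture; its p-values have an atom at 1
#' (about half of null windows sit on the boundary), which is why the score
#' test is the default.
#'
#' Windows of monomorphic SNPs have a zero kernel and get p = 1.
#'
#' @inheritParams single_snp_gwas
#' @param window_half Half-width of the window in SNPs (default 20, i.e. 41
#'   SNPs mid-chromosome).
#' @param slide Step between focal SNPs (default 1).
#' @param test `"score"` (default) or `"lrt"`.
#' @return Data frame of class `gwas_result`: `marker` (focal SNP),
#'   `chrom`, `pos`, `window_start`, `window_end`, `n_snps`, `p`,
#'   `neglog10p`, `fdr_sig`.
#' @export
snp_set_gwas <- function(geno, y, X = NULL, K = NULL, map = NULL,
                         window_half = 20, slide = 1,
                         test = c("score", "lrt"), fdr_q = 0.05) {
  test <- match.arg(test)
  n <- nrow(geno)
  m <- ncol(geno)
  stopifnot(length(y) == n)
  if (is.null(K)) K <- compute_kinship(geno)
  if (is.null(X)) X <- cbind(Intercept = 1, genotype_pcs(geno, k = min(3L, n - 2L)))
  if (is.null(map)) map <- data.frame(id = colnames(geno) %||% paste0("M", seq_len(m)),
                                      chrom = 1L, pos = seq_len(m))
  null <- fit_null_lmm(y, X, K)
  p_cov <- ncol(X)

  Gi <- mean_impute(geno)
  sds <- apply(Gi, 2L, stats::sd)
  Gs <- sweep(Gi, 2L, colMeans(Gi))
  pos_sd <- sds > 0
  Gs[, pos_sd] <- sweep(Gs[, pos_sd, drop = FALSE], 2L, sds[pos_sd], "/")
  Gs[, !pos_sd] <- 0

  sw <- sqrt(null$lambda * null$d + 1)
  Xw <- null$X_rot / sw
  yw <- null$y_rot / sw
  B <- crossprod(null$U, Gs) / sw
  Q <- qr(Xw)
  r <- qr.resid(Q, yw)
  Br <- qr.resid(Q, B)
  sc <- as.numeric(crossprod(Br, r))
  s2 <- sum(r^2) / (n - p_cov)

  focal <- integer(0)
  wins <- list()
  for (cc in unique(map$chrom)) {
    ix <- which(map$chrom == cc)
    fc <- ix[seq(1L, length(ix), by = slide)]
    lo <- pmax(match(fc, ix) - window_half, 1L)
    hi <- pmin(match(fc, ix) + window_half, length(ix))
    for (k in seq_along(fc)) {
      wins[[length(wins) + 1L]] <- ix[lo[k]:hi[k]]
    }
    focal <- c(focal, fc)
  }

  pval <- rep(NA_real_, length(focal))
  for (k in seq_along(focal)) {
    w <- wins[[k]]
    M <- crossprod(Br[, w, drop = FALSE])
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > max(ev[1] * 1e-10, 1e-12)]
    if (!length(ev)) { pval[k] <- 1; next }
    if (test == "score") {
      q_stat <- sum(sc[w]^2) / s2
      pval[k] <- weighted_chisq_p(q_stat, ev)
    } else {
      pval[k] <- window_lrt_p(yw, Xw, B[, w, drop = FALSE], n, p_cov)
    }
  }

  res <- data.frame(
    marker = map$id[focal],
    chrom = map$chrom[focal], pos = map$pos[focal],
    window_start = vapply(wins, function(w) map$pos[w[1]], numeric(1)),
    window_end = vapply(wins, function(w) map$pos[w[length(w)]], numeric(1)),
    n_snps = lengths(wins),
    p = pval,
    neglog10p = -log10(pmax(pval, 1e-300)),
    stringsAsFactors = FALSE
  )
  res$fdr_sig <- bh_fdr(res$p, q = fdr_q)$significant
  class(res) <- c("gwas_result", "data.frame")
  res
}

# P(sum lambda_j chi2_1j > q) by Imhof's integral, Liu fallback
#' @keywords internal
#' @noRd
weighted_chisq_p <- function(q, lambda) {
  f <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p(outer(lambda, u)^2))
    sin(th) / (u * exp(lrho))
  }
  p <- tryCatch({
    int <- stats::integrate(f, 0, Inf, rel.tol = 1e-9, subdivisions = 1000L,
                            stop.on.error = FALSE)
    0.5 + int$value / pi
  }, error = function(e) NA_real_)
  if (!is.finite(p) || p < -1e-4 || p > 1 + 1e-4) p <- liu_p(q, lambda)
  min(max(p, 1e-300), 1)
}

# Liu-Tang-Zhang moment-matched chi-square approximation
#' @keywords internal
#' @noRd
liu_p <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    df <- a^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- df + delta; sigma_x <- sqrt(2 * (df + 2 * delta))
  t_star <- (q - mu_q) / sigma_q
  stats::pchisq(t_star * sigma_x + mu_x, df = df, ncp = delta,
                lower.tail = FALSE)
}

# restricted LRT with 0.5 chi2_0 + 0.5 chi2_1 reference for one extra
# variance component; inputs already whitened by the null covariance
#' @keywords internal
#' @noRd
window_lrt_p <- function(yw, Xw, Z, n, p_cov) {
  ZtZ <- crossprod(Z)
  d <- eigen(ZtZ, symmetric = TRUE, only.values = TRUE)$values
  d <- pmax(d, 0)
  Zty <- crossprod(Z, yw)
  ZtX <- crossprod(Z, Xw)
  XtX <- crossprod(Xw)
  Xty <- crossprod(Xw, yw)
  yty <- sum(yw^2)
  ldet_xx <- determinant(XtX, logarithm = TRUE)$modulus

  ll_at <- function(lam) {
    if (lam == 0) {
      XWX <- XtX; XWy <- Xty; yWy <- yty; ldw <- 0
    } else {
      A <- ZtZ + diag(1 / lam, ncol(Z))
      Ai <- solve(A)
      XWX <- XtX - crossprod(ZtX, Ai %*% ZtX)
      XWy <- Xty - crossprod(ZtX, Ai %*% Zty)
      yWy <- yty - crossprod(Zty, Ai %*% Zty)
      ldw <- sum(log1p(lam * d))
    }
    beta <- solve(XWX, XWy)
    rss <- max(as.numeric(yWy - crossprod(XWy, beta)), 1e-300)
    sigma2 <- rss / (n - p_cov)
    ldet_xwx <- determinant(XWX, logarithm = TRUE)$modulus
    as.numeric(-0.5 * ((n - p_cov) * log(2 * pi * sigma2) + (n - p_cov) +
                         ldw + ldet_xwx - ldet_xx))
  }

  l0 <- ll_at(0)
  obj <- function(ll) -ll_at(exp(ll))
  grid <- seq(-12, 8, length.out = 21)
  vals <- vapply(grid, obj, numeric(1))
  i0 <- which.min(vals)
  opt <- stats::optimize(obj, c(grid[max(1L, i0 - 1L)], grid[min(21L, i0 + 1L)]))
  l1 <- max(-opt$objective, l0)
  stat <- 2 * (l1 - l0)
  if (stat <= 1e-10) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up multiple-testing correction at level `q`: flags every test whose
#' BH-adjusted p-value is at most `q`, and reports the raw-p threshold (the
#' largest flagged p-value).
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List: `significant` (logical flags), `threshold` (raw-p cutoff,
#'   NA when nothing is flagged), `adjusted` (BH-adjusted p-values).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) stopf("bh_fdr: empty p-value vector")
  adj <- stats::p.adjust(pvalues, method = "BH")
  sig <- !is.na(adj) & adj <= q
  list(significant = sig,
       threshold = if (any(sig)) max(pvalues[sig]) else NA_real_,
       adjusted = adj)
}
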