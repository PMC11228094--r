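#' Fit the null linear mixed model by REML (single kernel)
#'
#' Fits y = X beta + u + e with u ~ N(0, sigma2_g K) and
#' e ~ N(0, sigma2_e I) by restricted maximum likelihood, using the
#' spectral decomposition of K to reduce the problem to a one-dimensional
#' optimisation over the variance ratio lambda = sigma2_g / sigma2_e
#' (bracketed grid on log lambda followed by golden-section refinement).
#'
#' @param y Numeric response (finite; an error lists non-finite entries).
#' @param X Fixed-effect design matrix (typically an intercept plus
#'   principal-component scores); must have full column rank.
#' @param K Relatedness kernel (n x n symmetric PSD).
#' @return Object of class `lmm_fit`: `lambda`, `sigma2_g`, `sigma2_e`,
#'   `beta`, `loglik` (REML), and the cached spectral decomposition
#'   (`U`, `d`) plus rotated data for reuse by the association scans.
#' @export
fit_null_lmm <- function(y, X, K) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, n)
  bad <- which(!is.finite(y))
  if (length(bad)) {
    stopf("fit_null_lmm: non-finite response at position(s) %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  p <- ncol(X)
  if (qr(X)$rank < p) stopf("fit_null_lmm: X is rank-deficient")

  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  ldet_xx <- determinant(crossprod(X), logarithm = TRUE)$modulus

  obj <- function(log_lambda) -reml_ll_1k(exp(log_lambda), yr, Xr, d, ldet_xx)$ll
  grid <- seq(-10, 10, length.out = 41)
  vals <- vapply(grid, obj, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(obj, c(lo, hi))
  lambda <- exp(opt$minimum)
  fit <- reml_ll_1k(lambda, yr, Xr, d, ldet_xx)

  sigma2_e <- fit$sigma2
  if (sigma2_e < 1e-12) {
    warnf("fit_null_lmm: residual variance underflow (constant response?); flooring at 1e-12")
    sigma2_e <- 1e-12
  }
  structure(list(
    lambda = lambda, sigma2_g = lambda * sigma2_e, sigma2_e = sigma2_e,
    beta = fit$beta, loglik = fit$ll,
    U = U, d = d, y_rot = yr, X_rot = Xr, X = X, y = y, n = n, p = p,
    ldet_xx = ldet_xx
  ), class = "lmm_fit")
}

# REML log-likelihood and GLS solution for H = lambda K + I in the rotated
# basis; returns profile sigma2 (residual variance estimate)
#' @keywords internal
#' @noRd
reml_ll_1k <- function(lambda, yr, Xr, d, ldet_xx) {
  n <- length(yr); p <- ncol(Xr)
  w <- lambda * d + 1
  sw <- sqrt(w)
  Xw <- Xr / sw
  yw <- yr / sw
  qrx <- qr(Xw)
  beta <- qr.coef(qrx, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  if (sigma2 < 1e-300) sigma2 <- 1e-300
  R <- qr.R(qrx)
  ldet_xhx <- 2 * sum(log(abs(diag(R))))
  ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) +
                  sum(log(w)) + ldet_xhx - ldet_xx)
  list(ll = as.numeric(ll), beta = as.numeric(beta), sigma2 = sigma2,
       rss = rss, w = w)
}

#' Fit a multi-kernel linear mixed model by REML
#'
#' REML for y = X beta + u_1 + ... + u_q + e with u_j ~ N(0, sigma2_j K_j),
#' optimising the variance ratios lambda_j = sigma2_j / sigma2_e
#' numerically (Nelder-Mead on the log ratios; the single-kernel spectral
#' fit supplies the starting values). Used for the additive + dominance
#' genomic prediction models.
#'
#' @param y Numeric response.
#' @param X Fixed-effect design matrix.
#' @param kernels List of n x n relationship matrices.
#' @return Object of class `lmm_fit_mk`: `lambdas`, `sigma2` (named vector
#'   of kernel variances and `e` residual), `beta`, `loglik`, and `Hinv_r`
#'   (the weighted residual vector reused for BLUP back-solving).
#' @export
fit_lmm_multikernel <- function(y, X, kernels) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, n)
  q <- length(kernels)
  stopifnot(q >= 1L)
  p <- ncol(X)
  ldet_xx <- determinant(crossprod(X), logarithm = TRUE)$modulus

  nll <- function(log_lam) {
    lam <- exp(log_lam)
    H <- diag(1, n)
    for (j in seq_len(q)) H <- H + lam[j] * kernels[[j]]
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet_h <- 2 * sum(log(diag(ch)))
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    qrx <- qr(Xi)
    beta <- qr.coef(qrx, yi)
    rss <- sum((yi - Xi %*% beta)^2)
    sigma2 <- max(rss / (n - p), 1e-300)
    ldet_xhx <- 2 * sum(log(abs(diag(qr.R(qrx)))))
    0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) +
             ldet_h + ldet_xhx - ldet_xx)
  }

  # starting values from single-kernel fits
  start <- vapply(kernels, function(K) {
    f <- fit_null_lmm(y, X, K)
    log(max(f$lambda, 1e-6))
  }, numeric(1))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  lam <- exp(opt$par)

  H <- diag(1, n)
  for (j in seq_len(q)) H <- H + lam[j] * kernels[[j]]
  ch <- chol(H)
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  beta <- qr.coef(qr(Xi), yi)
  r <- y - X %*% beta
  Hinv_r <- backsolve(ch, backsolve(ch, r, transpose = TRUE))
  rss <- sum(backsolve(ch, r, transpose = TRUE)^2)
  sigma2_e <- max(rss / (n - p), 1e-12)

  structure(list(
    lambdas = lam,
    sigma2 = c(stats::setNames(lam * sigma2_e, names(kernels) %||% paste0("K", seq_len(q))),
               e = sigma2_e),
    beta = as.numeric(beta), loglik = -opt$value,
    Hinv_r = as.numeric(Hinv_r), X = X, y = y
  ), class = "lmm_fit_mk")
}
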