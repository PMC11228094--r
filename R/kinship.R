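#' Genomic (VanRaden) relationship matrix from dosage genotypes
#'
#' Computes G = W W' / (2 * sum p_k (1 - p_k)) where W is the dosage matrix
#' centered per marker at 2(p_k - 0.5) on the \{-1, 0, 1\} coding (aa, Aa,
#' AA). Missing entries are mean-imputed per marker; markers with zero
#' variance after filtering are excluded with a warning. A 1e-6 ridge is
#' added to the diagonal so the matrix stays numerically positive
#' semi-definite. The average diagonal is approximately 1 plus the mean
#' inbreeding of the population.
#'
#' @param geno Dosage matrix (individuals x markers).
#' @return Symmetric n x n relationship matrix.
#' @export
additive_kernel <- function(geno) {
  if (nrow(geno) < 2L) stopf("additive_kernel: need at least 2 individuals")
  p <- allele_freq(geno)
  keep <- !is.nan(p) & p > 0 & p < 1
  if (!all(keep)) {
    warnf("additive_kernel: excluding %d zero-variance marker(s)", sum(!keep))
    geno <- geno[, keep, drop = FALSE]
    p <- p[keep]
  }
  W <- mean_impute(geno)
  W <- sweep(W, 2L, 2 * (p - 0.5))
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  G + diag(1e-6, nrow(G))
}

#' @rdname additive_kernel
#' @export
compute_kinship <- additive_kernel

#' Dominance relationship matrix
#'
#' Classical heterozygosity-coded dominance matrix: H_ik is the
#' heterozygote indicator minus its Hardy-Weinberg expectation 2 p_k q_k,
#' and D = H H' / sum_k 2 p_k q_k (1 - 2 p_k q_k). Missing genotypes
#' contribute their expected heterozygosity. Under Hardy-Weinberg
#' equilibrium D is uncorrelated with the additive matrix. If the
#' population carries no heterozygous calls at all, the zero matrix is
#' returned with a warning.
#'
#' @param geno Dosage matrix (individuals x markers).
#' @return Symmetric n x n dominance relationship matrix.
#' @export
dominance_kernel <- function(geno) {
  if (nrow(geno) < 2L) stopf("dominance_kernel: need at least 2 individuals")
  p <- allele_freq(geno)
  keep <- !is.nan(p) & p > 0 & p < 1
  geno <- geno[, keep, drop = FALSE]
  p <- p[keep]
  if (!ncol(geno) || !any(geno == 0L, na.rm = TRUE)) {
    warnf("dominance_kernel: no heterozygous calls; returning the zero matrix")
    return(matrix(0, nrow(geno), nrow(geno),
                  dimnames = list(rownames(geno), rownames(geno))))
  }
  twopq <- 2 * p * (1 - p)
  H <- (geno == 0L) * 1
  idx <- which(is.na(geno), arr.ind = TRUE)
  if (nrow(idx)) H[idx] <- twopq[idx[, 2L]]
  H <- sweep(H, 2L, twopq)
  denom <- sum(twopq * (1 - twopq))
  D <- tcrossprod(H) / denom
  D + diag(1e-6, nrow(D))
}

#' Principal components of the genotype matrix
#'
#' Top-k eigenvectors of the centered genotype covariance (missing entries
#' mean-imputed), returned as per-individual scores. Used as fixed
#' covariates to absorb population structure in association models.
#'
#' @param geno Dosage matrix (individuals x markers).
#' @param k Number of components (must be < n).
#' @return n x k matrix of PC scores (columns `PC1`..`PCk`).
#' @export
genotype_pcs <- function(geno, k = 3) {
  n <- nrow(geno)
  if (k >= n) stopf("genotype_pcs: k (%d) must be smaller than n (%d)", k, n)
  X <- mean_impute(geno)
  X <- sweep(X, 2L, colMeans(X))
  sv <- svd(X, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(geno), paste0("PC", seq_len(k)))
  scores
}
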