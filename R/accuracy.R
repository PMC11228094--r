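#' Genotype score accuracy over masked cells
#'
#' Fraction of masked cells at which the imputed dosage score (1, 0, -1)
#' equals the true score. Masked cells left missing by the imputation count
#' as errors.
#'
#' @param imputed Imputed dosage matrix.
#' @param truth True dosage matrix of the same shape.
#' @param mask Logical matrix: the evaluated cells.
#' @return A fraction in [0, 1].
#' @export
score_accuracy <- function(imputed, truth, mask) {
  stopifnot(all(dim(imputed) == dim(truth)), all(dim(mask) == dim(truth)))
  if (!any(mask)) stopf("score_accuracy: empty mask")
  mean(!is.na(imputed[mask]) & imputed[mask] == truth[mask])
}

#' Phasing accuracy against true parental transmission
#'
#' Over the truly heterozygous markers of each evaluated individual, the
#' fraction at which the allele assigned to the female-parent-labelled
#' haplotype equals the truly maternally transmitted allele, averaged over
#' individuals. Individuals without heterozygous markers are excluded and
#' counted.
#'
#' @param est_h1 Estimated female-parent-labelled haplotype matrix
#'   (individuals x markers, 0/1).
#' @param truth_h1 True maternal haplotype matrix.
#' @param truth_geno True dosage matrix (used to locate heterozygous
#'   markers).
#' @return List: `accuracy` (mean over individuals), `per_individual`,
#'   `n_excluded`.
#' @export
phasing_accuracy <- function(est_h1, truth_h1, truth_geno) {
  stopifnot(all(dim(est_h1) == dim(truth_h1)),
            all(dim(truth_geno) == dim(truth_h1)))
  acc <- vapply(seq_len(nrow(est_h1)), function(i) {
    het <- truth_geno[i, ] == 0L
    if (!any(het)) return(NA_real_)
    mean(est_h1[i, het] == truth_h1[i, het])
  }, numeric(1))
  list(accuracy = mean(acc, na.rm = TRUE),
       per_individual = acc,
       n_excluded = sum(is.na(acc)))
}
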