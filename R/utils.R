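# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0 && x == round(x)
}

is_rate <- function(x) is.numeric(x) & is.finite(x) & x >= 0 & x <= 1

#' @keywords internal
#' @noRd
order_map <- function(map) {
  map[order(map$chrom, map$pos), , drop = FALSE]
}

# dosage {1,0,-1} -> allele count of the reference ("A") allele in 0..2
dosage_to_count <- function(x) x + 1L

# per-marker frequency of the "A" allele from dosage codes
allele_freq <- function(geno) {
  colMeans(dosage_to_count(geno), na.rm = TRUE) / 2
}

# mean-impute missing dosages per marker (columns)
mean_impute <- function(geno) {
  mu <- colMeans(geno, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(geno), arr.ind = TRUE)
  if (nrow(idx)) geno[idx] <- mu[idx[, 2L]]
  geno
}
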