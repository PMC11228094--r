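#' Filter markers by minor allele frequency
#'
#' Removes markers whose minor allele frequency, computed on non-missing
#' calls, is below the threshold. Markers with no non-missing calls are
#' treated as monomorphic (MAF 0) and removed at any positive threshold.
#'
#' @param geno Dosage matrix (individuals x markers).
#' @param map Marker map matching the columns of `geno`.
#' @param threshold MAF threshold in [0, 0.5]; markers with MAF `<`
#'   threshold are dropped. The conventional genome-wide-association default
#'   is 0.025.
#' @return List with the filtered `geno` and `map` plus `removed` (marker
#'   ids) and `maf` (the frequencies of the retained markers).
#' @export
filter_maf <- function(geno, map, threshold = 0.025) {
  if (!(length(threshold) == 1L && threshold >= 0 && threshold <= 0.5)) {
    stopf("filter_maf: threshold must be in [0, 0.5]")
  }
  p <- allele_freq(geno)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0          # markers with all calls missing
  keep <- if (threshold == 0) rep(TRUE, length(maf)) else maf >= threshold
  if (!any(keep)) stopf("filter_maf: all markers removed at threshold %g", threshold)
  list(geno = geno[, keep, drop = FALSE],
       map = map[keep, , drop = FALSE],
       removed = map$id[!keep],
       maf = maf[keep])
}
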