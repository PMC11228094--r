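#' Estimate the parental origin of a phased haplotype by window voting
#'
#' Classifies a phased offspring haplotype as dam- or sire-derived by
#' repeated local correlation: in each repetition a window of `n_markers`
#' consecutive markers is drawn at random (uniformly over the chromosomes
#' long enough to hold it, then uniformly within the chromosome), the
#' Pearson correlation between the offspring haplotype and each of the four
#' parental haplotypes is computed over the window, and the repetition votes
#' for the parent owning the best-correlated haplotype. The final label is
#' the parent with the majority of votes; an exact tie returns `"unknown"`.
#'
#' Windows in which the offspring haplotype has zero variance (monomorphic
#' stretch) are discarded and redrawn, up to `10 * reps` attempts in total;
#' if no valid window can be drawn the label is `"unknown"`.
#'
#' @param offspring_hap Numeric/integer vector of 0/1 alleles over the map.
#' @param parent_haps List with `dam` and `sire` 2 x m haplotype matrices.
#' @param marker_map Marker map (`id`, `chrom`, `pos`).
#' @param n_markers Window length in consecutive markers (default 30).
#' @param reps Number of window draws (default 100).
#' @param seed Optional integer seed for the window draws.
#' @return List: `label` (`"female"`, `"male"` or `"unknown"`), `votes`
#'   (named counts), `n_valid` (repetitions that yielded a vote).
#' @export
estimate_parental_origin <- function(offspring_hap, parent_haps, marker_map,
                                     n_markers = 30, reps = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(offspring_hap)
  stopifnot(nrow(marker_map) == m)
  chroms <- unique(marker_map$chrom)
  sizes <- vapply(chroms, function(cc) sum(marker_map$chrom == cc), integer(1))
  eligible <- chroms[sizes >= n_markers]
  if (!length(eligible)) {
    stopf("estimate_parental_origin: no chromosome has >= %d markers", n_markers)
  }
  starts <- lapply(eligible, function(cc) {
    ix <- which(marker_map$chrom == cc)
    ix[seq_len(length(ix) - n_markers + 1L)]
  })
  names(starts) <- as.character(eligible)

  haps <- rbind(parent_haps$dam, parent_haps$sire)  # rows: d1 d2 s1 s2
  votes <- c(female = 0L, male = 0L)
  n_valid <- 0L
  attempts <- 0L
  max_attempts <- 10L * reps
  while (n_valid < reps && attempts < max_attempts) {
    attempts <- attempts + 1L
    cc <- as.character(eligible[sample.int(length(eligible), 1L)])
    st <- starts[[cc]][sample.int(length(starts[[cc]]), 1L)]
    w <- st:(st + n_markers - 1L)
    x <- offspring_hap[w]
    if (stats::sd(x) == 0) next
    r <- apply(haps[, w, drop = FALSE], 1L, function(h) {
      if (stats::sd(h) == 0) return(NA_real_)
      stats::cor(x, h)
    })
    if (all(is.na(r))) next
    best <- which.max(r)
    votes[if (best <= 2L) "female" else "male"] <-
      votes[if (best <= 2L) "female" else "male"] + 1L
    n_valid <- n_valid + 1L
  }
  label <- if (n_valid == 0L || votes["female"] == votes["male"]) {
    "unknown"
  } else if (votes["female"] > votes["male"]) "female" else "male"
  list(label = label, votes = votes, n_valid = n_valid)
}
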