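#' Additive (numerator) relationship matrix from a pedigree
#'
#' Builds Wright's numerator relationship matrix A by the tabular method:
#' individuals are processed in topological order, each off-diagonal entry is
#' the average of the relationships with the individual's two parents, and
#' each diagonal is 1 plus half the parents' relationship. Founders are
#' assumed unrelated and non-inbred.
#'
#' @param pedigree Data frame with `id`, `sire`, `dam` (NA for founders).
#' @return A symmetric n x n matrix with the pedigree ids as dimnames.
#' @export
additive_relationship <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Pedigree-based inbreeding coefficients
#'
#' Wright-consistent inbreeding coefficients F = A_ii - 1 from the tabular
#' additive-relationship recursion. Founders (individuals with unknown
#' parents) get F = 0; because unrecorded ancestral inbreeding is thereby
#' ignored, pedigree F systematically understates genomic inbreeding in
#' populations whose founders were themselves related.
#'
#' @param pedigree Data frame with `id`, `sire`, `dam` and optionally
#'   `crossing_year` / `registration_year` (carried through).
#' @return Data frame `id`, `F_pedigree` (plus any year columns present),
#'   in the pedigree's topological order.
#' @export
pedigree_inbreeding <- function(pedigree) {
  A <- additive_relationship(pedigree)
  out <- data.frame(id = rownames(A), F_pedigree = diag(A) - 1,
                    stringsAsFactors = FALSE)
  for (col in c("crossing_year", "registration_year")) {
    if (col %in% names(pedigree)) {
      out[[col]] <- pedigree[[col]][match(out$id, pedigree$id)]
    }
  }
  rownames(out) <- NULL
  out
}
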