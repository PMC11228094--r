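#' Merge genotype matrices from two platforms by physical position
#'
#' Combines two marker panels that share a reference coordinate system into
#' one genotype matrix. The merge key is (chromosome, position). At
#' positions genotyped by both platforms the copy from the platform with the
#' higher overall missing rate is dropped (ties drop the second panel's
#' copy), after recording the genotype consistency of the duplicated markers:
#' for each shared position, the fraction of individuals genotyped on both
#' platforms whose calls agree, averaged over the shared markers.
#' Individuals present on only one platform receive missing entries for the
#' other platform's markers.
#'
#' @param genoA,genoB Dosage matrices (individuals x markers, entries in
#'   \{1, 0, -1, NA\}) with marker ids as column names.
#' @param mapA,mapB Marker maps (`id`, `chrom`, `pos`, `platform`) matching
#'   the matrices.
#' @return List with:
#'   \describe{
#'     \item{geno}{merged dosage matrix over the union of individuals and
#'       retained markers, sorted by (chromosome, position).}
#'     \item{map}{merged marker map with the source platform tag of each
#'       retained marker.}
#'     \item{overlap}{list: `n` shared positions, `mean_consistency`,
#'       per-marker consistency table, and the ids of the dropped copies.}
#'   }
#' @export
merge_platforms <- function(genoA, mapA, genoB, mapB) {
  check_geno_map(genoA, mapA, "A")
  check_geno_map(genoB, mapB, "B")

  # empty-panel merges are the identity
  if (nrow(mapB) == 0L) {
    return(list(geno = genoA, map = order_map(mapA),
                overlap = list(n = 0L, mean_consistency = NA_real_,
                               per_marker = NULL, dropped = character(0))))
  }
  if (nrow(mapA) == 0L) {
    return(list(geno = genoB, map = order_map(mapB),
                overlap = list(n = 0L, mean_consistency = NA_real_,
                               per_marker = NULL, dropped = character(0))))
  }
  chA <- unique(mapA$chrom); chB <- unique(mapB$chrom)
  if (length(intersect(chA, chB)) == 0L) {
    stopf("merge_platforms: no common chromosome names; unmatched: [%s] vs [%s]",
          paste(chA, collapse = ","), paste(chB, collapse = ","))
  }

  keyA <- paste(mapA$chrom, mapA$pos)
  keyB <- paste(mapB$chrom, mapB$pos)
  shared <- intersect(keyA, keyB)
  missA <- mean(is.na(genoA))
  missB <- mean(is.na(genoB))

  overlap <- list(n = length(shared), mean_consistency = NA_real_,
                  per_marker = NULL, dropped = character(0))
  if (length(shared)) {
    ids_both <- intersect(rownames(genoA), rownames(genoB))
    iA <- match(shared, keyA); iB <- match(shared, keyB)
    cons <- rep(NA_real_, length(shared))
    if (length(ids_both)) {
      gA <- genoA[ids_both, iA, drop = FALSE]
      gB <- genoB[ids_both, iB, drop = FALSE]
      ok <- !is.na(gA) & !is.na(gB)
      agree <- colSums(ok & (gA == gB))
      tot <- colSums(ok)
      cons <- ifelse(tot > 0, agree / tot, NA_real_)
    }
    overlap$per_marker <- data.frame(
      chrom = mapA$chrom[iA], pos = mapA$pos[iA],
      id_A = mapA$id[iA], id_B = mapB$id[iB],
      consistency = cons, stringsAsFactors = FALSE
    )
    overlap$mean_consistency <- mean(cons, na.rm = TRUE)
    # drop the copy from the platform with the higher overall missing rate
    if (missA > missB) {
      overlap$dropped <- mapA$id[iA]
      keepA <- !(keyA %in% shared)
      keepB <- rep(TRUE, nrow(mapB))
    } else {
      overlap$dropped <- mapB$id[iB]
      keepA <- rep(TRUE, nrow(mapA))
      keepB <- !(keyB %in% shared)
    }
  } else {
    keepA <- rep(TRUE, nrow(mapA))
    keepB <- rep(TRUE, nrow(mapB))
  }

  map <- rbind(mapA[keepA, , drop = FALSE], mapB[keepB, , drop = FALSE])
  if (anyDuplicated(paste(map$chrom, map$pos))) {
    stopf("merge_platforms: duplicated positions within a single platform")
  }
  map <- order_map(map)
  rownames(map) <- NULL

  ids <- union(rownames(genoA), rownames(genoB))
  geno <- matrix(NA_integer_, length(ids), nrow(map),
                 dimnames = list(ids, map$id))
  fromA <- map$id %in% mapA$id[keepA]
  geno[match(rownames(genoA), ids), map$id[fromA]] <-
    genoA[, map$id[fromA], drop = FALSE]
  geno[match(rownames(genoB), ids), map$id[!fromA]] <-
    genoB[, map$id[!fromA], drop = FALSE]

  list(geno = geno, map = map, overlap = overlap)
}

#' @keywords internal
#' @noRd
check_geno_map <- function(geno, map, label) {
  if (!is.matrix(geno)) stopf("merge_platforms: geno%s must be a matrix", label)
  if (!all(c("id", "chrom", "pos") %in% names(map))) {
    stopf("merge_platforms: map%s needs columns id, chrom, pos", label)
  }
  if (ncol(geno) != nrow(map) ||
      (nrow(map) > 0L && !identical(colnames(geno), map$id))) {
    stopf("merge_platforms: geno%s columns do not match map%s ids", label, label)
  }
  if (anyDuplicated(paste(map$chrom, map$pos))) {
    stopf("merge_platforms: map%s has duplicated positions", label)
  }
  invisible(TRUE)
}
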