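#' Define a masking scheme over (individual, platform) blocks
#'
#' A masking scheme names a set of (individual, platform) cells whose
#' genotypes are to be withheld ("masked with NA") from a merged genotype
#' matrix, emulating individuals that were never genotyped on one of the
#' platforms. Masking the withheld cells and then recovering them by
#' family-based imputation is the accuracy-evaluation design used throughout
#' the package.
#'
#' @param label Dataset label (1, 2 or 3 in the standard evaluation design,
#'   but any scalar is accepted).
#' @param ids Individuals to mask.
#' @param platform Platform tag(s) (`"A"` or `"B"`), recycled over `ids`.
#' @return An object of class `mask_scheme`: list with `label` and `cells`
#'   (data frame `id`, `platform`).
#' @export
mask_scheme <- function(label, ids, platform) {
  cells <- data.frame(id = as.character(ids),
                      platform = rep_len(as.character(platform), length(ids)),
                      stringsAsFactors = FALSE)
  structure(list(label = label, cells = unique(cells)), class = "mask_scheme")
}

#' Standard evaluation masking schemes (Datasets 1-3)
#'
#' Builds the scheme for the three-dataset masking design used to measure
#' phasing and imputation accuracy:
#' \describe{
#'   \item{Dataset 1}{platform-B genotypes of the dual-genotyped families are
#'     masked (recovered from the platform-A scaffold).}
#'   \item{Dataset 2}{platform-A genotypes of the dual-genotyped families are
#'     masked (recovered from the platform-B scaffold).}
#'   \item{Dataset 3}{same masking as Dataset 2, applied to the full
#'     population in which the remaining families carry platform-A data
#'     only, mimicking a program part-way through a platform switch.}
#' }
#'
#' @param pedigree A pedigree with `role`, `dual` and `family` columns (as
#'   produced by [simulate_pedigree()]).
#' @param dataset 1, 2 or 3.
#' @return A `mask_scheme`.
#' @export
dataset_scheme <- function(pedigree, dataset) {
  if (!dataset %in% 1:3) stopf("dataset_scheme: dataset must be 1, 2 or 3")
  dual_off <- pedigree$id[pedigree$role == "offspring" & pedigree$dual]
  if (!length(dual_off)) stopf("dataset_scheme: no dual-genotyped offspring in pedigree")
  platform <- if (dataset == 1) "B" else "A"
  mask_scheme(dataset, dual_off, platform)
}

#' Individuals included in each evaluation dataset
#'
#' Datasets 1 and 2 contain the parental population plus the dual-genotyped
#' families; Dataset 3 contains the whole population.
#'
#' @param pedigree A pedigree with `role` and `dual` columns.
#' @param dataset 1, 2 or 3.
#' @return Character vector of individual ids.
#' @export
dataset_individuals <- function(pedigree, dataset) {
  if (!dataset %in% 1:3) stopf("dataset_individuals: dataset must be 1, 2 or 3")
  if (dataset == 3) return(pedigree$id)
  pedigree$id[pedigree$role == "parent" | pedigree$dual]
}

#' Apply a masking scheme to a merged genotype matrix
#'
#' Sets every genotype cell named by the scheme to missing and leaves
#' everything else untouched. A cell block (individual, platform) covers all
#' retained markers whose source tag is that platform.
#'
#' @param geno Merged dosage matrix.
#' @param scheme A [mask_scheme()].
#' @param map Merged marker map with the `platform` source tags.
#' @return The masked matrix, with attributes `n_masked` (genotype cells
#'   newly set to NA), `n_prev_missing` (cells in the scheme that were
#'   already missing) and `scheme_label`.
#' @export
build_masked_dataset <- function(geno, scheme, map) {
  stopifnot(inherits(scheme, "mask_scheme"))
  bad <- setdiff(scheme$cells$id, rownames(geno))
  if (length(bad)) {
    stopf("build_masked_dataset: scheme ids absent from the matrix: %s",
          paste(bad, collapse = ", "))
  }
  n_masked <- 0L; n_prev <- 0L
  for (p in unique(scheme$cells$platform)) {
    cols <- map$id[map$platform == p]
    if (!length(cols)) next
    rows <- scheme$cells$id[scheme$cells$platform == p]
    blk <- geno[rows, cols, drop = FALSE]
    n_prev <- n_prev + sum(is.na(blk))
    n_masked <- n_masked + sum(!is.na(blk))
    geno[rows, cols] <- NA_integer_
  }
  attr(geno, "n_masked") <- n_masked
  attr(geno, "n_prev_missing") <- n_prev
  attr(geno, "scheme_label") <- scheme$label
  geno
}
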