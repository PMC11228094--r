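#' Impute masked genotypes from parental-origin paths
#'
#' Reconstructs masked genotype cells as the sum of the two parental alleles
#' copied at the marker along the offspring's parental-origin paths, on the
#' dosage scale \{1, 0, -1\}. Cells whose origin is unknown at a masked
#' marker are left missing and counted.
#'
#' @param origin_path List with `o1`, `o2` origin matrices (offspring x m,
#'   values 1/2 or NA), as returned by [phase_family()].
#' @param parent_haps List with `dam` and `sire` 2 x m haplotype matrices.
#' @param mask Logical matrix (offspring x m): cells to impute.
#' @return List: `geno` (matrix with imputed dosages at masked cells, NA
#'   elsewhere), `n_unimputed` (masked cells with unknown origin).
#' @export
impute_from_origin <- function(origin_path, parent_haps, mask) {
  o1 <- origin_path$o1; o2 <- origin_path$o2
  stopifnot(is.matrix(mask), all(dim(mask) == dim(o1)))
  n <- nrow(o1); m <- ncol(o1)
  colix <- rep(seq_len(m), each = n)
  a1 <- matrix(parent_haps$dam[cbind(as.vector(o1), colix)], n, m)
  a2 <- matrix(parent_haps$sire[cbind(as.vector(o2), colix)], n, m)
  imputed <- a1 + a2 - 1L
  out <- matrix(NA_integer_, n, m, dimnames = dimnames(o1))
  out[mask] <- imputed[mask]
  list(geno = out, n_unimputed = sum(mask & is.na(imputed)))
}

#' Phasing and imputation accuracy on a masked evaluation dataset
#'
#' End-to-end evaluation wrapper for a simulated study: merges the two
#' observed platform matrices, applies the Dataset 1/2/3 masking scheme,
#' phases every dual-genotyped family against its (truth-phased) parents
#' with [phase_family()], imputes the masked cells from the inferred origin
#' paths, and scores the result against the simulation truth.
#'
#' @param sim A `breeding_sim` from [simulate_study()].
#' @param dataset 1, 2 or 3 (see [dataset_scheme()]).
#' @param penalty Crossover penalty for the family DP.
#' @return List of class `accuracy_report`: `dataset`, `phasing_accuracy`,
#'   `score_accuracy`, `n_masked_cells`, `n_unimputed` and a `per_family`
#'   data frame.
#' @export
evaluate_imputation <- function(sim, dataset, penalty = 2.5) {
  stopifnot(inherits(sim, "breeding_sim"))
  ped <- sim$pedigree
  merged <- merge_platforms(sim$geno$A, sim$maps$A, sim$geno$B, sim$maps$B)
  ids <- dataset_individuals(ped, dataset)
  geno <- merged$geno[intersect(rownames(merged$geno), ids), , drop = FALSE]
  scheme <- dataset_scheme(ped, dataset)
  masked <- build_masked_dataset(geno, scheme, merged$map)

  tmap_ix <- match(merged$map$id, sim$truth$map$id)
  truth_h1 <- sim$truth$hap$h1[, tmap_ix, drop = FALSE]
  truth_h2 <- sim$truth$hap$h2[, tmap_ix, drop = FALSE]
  truth_dose <- truth_h1 + truth_h2 - 1L

  mask_platform <- if (dataset == 1) "B" else "A"
  mask_cols <- merged$map$platform == mask_platform

  fams <- unique(ped$family[ped$role == "offspring" & ped$dual])
  per_fam <- vector("list", length(fams))
  tot_correct <- 0L; tot_cells <- 0L; tot_unimp <- 0L
  phase_acc_ind <- numeric(0)

  for (fi in seq_along(fams)) {
    fam <- fams[fi]
    off <- ped$id[!is.na(ped$family) & ped$family == fam]
    off <- intersect(off, rownames(masked))
    dam_id <- ped$dam[match(off[1], ped$id)]
    sire_id <- ped$sire[match(off[1], ped$id)]
    tr <- match(c(dam_id, sire_id), rownames(truth_h1))
    parent_haps <- list(
      dam = rbind(truth_h1[tr[1], ], truth_h2[tr[1], ]),
      sire = rbind(truth_h1[tr[2], ], truth_h2[tr[2], ])
    )
    ph <- phase_family(parent_haps, masked[off, , drop = FALSE],
                       merged$map, penalty = penalty)

    # score accuracy on the scheme-masked cells of this family
    mask <- matrix(FALSE, length(off), ncol(masked), dimnames = list(off, colnames(masked)))
    was_obs <- !is.na(geno[off, , drop = FALSE])
    mask[, mask_cols] <- was_obs[, mask_cols]
    imp <- impute_from_origin(ph, parent_haps, mask)
    tr_off <- match(off, rownames(truth_dose))
    tt <- truth_dose[tr_off, , drop = FALSE]
    correct <- sum(!is.na(imp$geno[mask]) & imp$geno[mask] == tt[mask])
    tot_correct <- tot_correct + correct
    tot_cells <- tot_cells + sum(mask)
    tot_unimp <- tot_unimp + imp$n_unimputed

    # phasing accuracy at truly heterozygous markers
    het <- tt == 0L
    th1 <- truth_h1[tr_off, , drop = FALSE]
    pacc <- vapply(seq_along(off), function(i) {
      hh <- het[i, ]
      if (!any(hh)) return(NA_real_)
      mean(ph$h1[i, hh] == th1[i, hh])
    }, numeric(1))
    phase_acc_ind <- c(phase_acc_ind, pacc)

    per_fam[[fi]] <- data.frame(
      family = fam, n_offspring = length(off),
      score_accuracy = ifelse(sum(mask) > 0, correct / sum(mask), NA_real_),
      phasing_accuracy = mean(pacc, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    dataset = dataset,
    score_accuracy = if (tot_cells > 0) tot_correct / tot_cells else NA_real_,
    phasing_accuracy = mean(phase_acc_ind, na.rm = TRUE),
    n_masked_cells = tot_cells,
    n_unimputed = tot_unimp,
    n_excluded_no_het = sum(is.na(phase_acc_ind)),
    per_family = do.call(rbind, per_fam)
  ), class = "accuracy_report")
}
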