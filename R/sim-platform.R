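#' Observe a truth set through one genotyping platform
#'
#' Restricts the true genotypes to the markers of one platform, recodes them
#' on the dosage scale (1 = AA, 0 = Aa, -1 = aa), and applies the platform's
#' missing-call rate (and, if configured, its random miscall rate — off by
#' default).
#'
#' @param truth A `truth_set`.
#' @param platform_index 1/`"A"` (array-like panel) or 2/`"B"`
#'   (sequencing-based panel).
#' @param config The [sim_config()].
#' @param ids Individuals genotyped on this platform (default: all
#'   individuals in the truth set).
#' @return List with `geno` (dosage matrix individuals x platform markers,
#'   NA = missing) and `map` (the platform's marker map, `platform` column
#'   set to the platform tag).
#' @export
apply_platform <- function(truth, platform_index, config, ids = truth$ids) {
  validate_sim_config(config)
  plat <- if (is.character(platform_index)) toupper(platform_index) else c("A", "B")[platform_index]
  if (!plat %in% c("A", "B")) stopf("apply_platform: platform must be 'A'/1 or 'B'/2")
  pi_num <- if (plat == "A") 1L else 2L
  set.seed(config$seed + 3L + pi_num)

  keep <- truth$map$platform %in% c(plat, "AB")
  map <- truth$map[keep, , drop = FALSE]
  map$platform <- plat
  rows <- match(ids, truth$ids)
  if (anyNA(rows)) {
    stopf("apply_platform: ids not in truth set: %s",
          paste(ids[is.na(rows)], collapse = ", "))
  }
  geno <- truth$hap$h1[rows, keep, drop = FALSE] +
    truth$hap$h2[rows, keep, drop = FALSE] - 1L
  dimnames(geno) <- list(ids, map$id)

  err <- config$geno_error_rate[pi_num]
  if (err > 0) {
    flip <- which(stats::runif(length(geno)) < err)
    if (length(flip)) {
      # replace by one of the two other codes, uniformly
      shift <- sample(1:2, length(flip), replace = TRUE)
      geno[flip] <- ((geno[flip] + 1L + shift) %% 3L) - 1L
    }
  }
  mr <- config$missing_rate[pi_num]
  if (mr > 0) {
    geno[stats::runif(length(geno)) < mr] <- NA_integer_
  }
  list(geno = geno, map = map)
}

#' Simulate a complete two-platform breeding study
#'
#' One-call wrapper around the generator: pedigree, founder haplotypes,
#' gamete dropping, phenotypes, and the two observed platform genotype
#' matrices. Platform A (array-like) covers every individual; platform B
#' (sequencing-based) covers the parental population and the dual-genotyped
#' families only, mirroring a program part-way through a platform switch.
#'
#' @param config A [sim_config()].
#' @param architecture A [trait_architecture()].
#' @return A list of class `breeding_sim` with elements `config`, `pedigree`,
#'   `truth`, `geno` (list `A`, `B`), `maps` (list `A`, `B`),
#'   `phen` (a `phenotype_sim`), and `F_true`.
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(n_founders = 8, n_families = 4,
#'                                  n_chromosomes = 3,
#'                                  markers_per_platform = c(120, 110),
#'                                  overlap_markers = 4))
#' }
#' @export
simulate_study <- function(config = sim_config(),
                           architecture = trait_architecture()) {
  ped <- simulate_pedigree(config)
  founders <- simulate_founders(config)
  truth <- drop_gametes(ped, founders, config)
  phen <- simulate_phenotypes(truth, architecture, ped, seed = config$seed + 11L)

  ids_B <- ped$id[ped$dual]
  pA <- apply_platform(truth, "A", config)                 # everyone
  pB <- apply_platform(truth, "B", config, ids = ids_B)    # parents + dual families

  structure(list(
    config = config, pedigree = ped, truth = truth,
    geno = list(A = pA$geno, B = pB$geno),
    maps = list(A = pA$map, B = pB$map),
    phen = phen,
    F_true = stats::setNames(true_inbreeding(truth), truth$ids)
  ), class = "breeding_sim")
}
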