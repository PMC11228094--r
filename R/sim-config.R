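#' Simulation configuration for a pedigreed two-platform breeding population
#'
#' Bundles and validates every dimension of the synthetic breeding population:
#' founder count, number of parent generations bred among the parental
#' population, number of full-sib families, marker panel sizes for the two
#' genotyping platforms, their overlap and missingness, and the meiotic
#' recombination rate.
#'
#' The defaults are a desk-scale (roughly 1/10) rendition of a typical apple
#' breeding program analysed with two genotyping platforms: 17 chromosomes of
#' 30 Mb, one array-like panel of 1,100 markers with 0.5% missing calls
#' (platform A) and one sequencing-based panel of 1,050 markers with 1.6%
#' missing calls (platform B), 9 markers shared by both panels, a parental
#' population descended from 20 founders, and 21 full-sib families of which 5
#' are genotyped on both platforms.
#'
#' @param n_founders Number of unrelated founder individuals.
#' @param n_parent_generations Generations of crosses bred among the parental
#'   population before the full-sib families are made.
#' @param n_families Number of full-sib (biparental F1) families.
#' @param family_size_range Length-2 integer vector, min and max family size.
#' @param n_dual_families Number of families genotyped on both platforms;
#'   the remaining families are genotyped on platform A only.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param markers_per_platform Length-2 counts `(countA, countB)` of markers
#'   on platforms A and B (including the shared markers).
#' @param overlap_markers Number of markers present on both platforms.
#' @param missing_rate Length-2 rates `(rateA, rateB)` of missing genotype
#'   calls per platform.
#' @param geno_error_rate Length-2 rates of random genotype miscalls per
#'   platform (a hook; default 0, i.e. missingness is the only noise).
#' @param recomb_rate Expected number of crossovers per chromosome per
#'   meiosis (Poisson mean).
#' @param seed Integer seed; the whole truth set is reproducible from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_founders = 4, n_families = 2,
#'                   markers_per_platform = c(60, 50), overlap_markers = 5,
#'                   n_chromosomes = 2)
#' @export
sim_config <- function(n_founders = 20,
                       n_parent_generations = 2,
                       n_families = 21,
                       family_size_range = c(4L, 16L),
                       n_dual_families = 5,
                       n_chromosomes = 17,
                       chrom_length_bp = 30e6,
                       markers_per_platform = c(1100L, 1050L),
                       overlap_markers = 9,
                       missing_rate = c(0.005, 0.016),
                       geno_error_rate = c(0, 0),
                       recomb_rate = 1.5,
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_parent_generations = as.integer(n_parent_generations),
    n_families = as.integer(n_families),
    family_size_range = as.integer(family_size_range),
    n_dual_families = as.integer(n_dual_families),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    markers_per_platform = as.integer(markers_per_platform),
    overlap_markers = as.integer(overlap_markers),
    missing_rate = as.numeric(missing_rate),
    geno_error_rate = as.numeric(geno_error_rate),
    recomb_rate = as.numeric(recomb_rate),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  counts <- c("n_founders", "n_parent_generations", "n_families",
              "n_dual_families", "n_chromosomes")
  for (nm in counts) {
    if (!is_count(cfg[[nm]]) && !(nm == "n_parent_generations" && cfg[[nm]] == 0L) &&
        !(nm == "n_dual_families" && cfg[[nm]] == 0L)) {
      stopf("sim_config: '%s' must be a positive count (got %s)", nm, cfg[[nm]])
    }
  }
  if (length(cfg$family_size_range) != 2L || any(cfg$family_size_range < 1L) ||
      cfg$family_size_range[1] > cfg$family_size_range[2]) {
    stopf("sim_config: 'family_size_range' must be an increasing pair of positive counts")
  }
  if (cfg$n_dual_families > cfg$n_families) {
    stopf("sim_config: n_dual_families (%d) exceeds n_families (%d)",
          cfg$n_dual_families, cfg$n_families)
  }
  if (!(length(cfg$chrom_length_bp) == 1L && cfg$chrom_length_bp > 0)) {
    stopf("sim_config: 'chrom_length_bp' must be a positive length")
  }
  if (length(cfg$markers_per_platform) != 2L || any(cfg$markers_per_platform < 1L)) {
    stopf("sim_config: 'markers_per_platform' must be two positive counts")
  }
  if (!(length(cfg$overlap_markers) == 1L && cfg$overlap_markers >= 0L)) {
    stopf("sim_config: 'overlap_markers' must be a non-negative count")
  }
  if (cfg$overlap_markers > min(cfg$markers_per_platform)) {
    stopf("sim_config: overlap_markers (%d) exceeds the smaller panel (%d)",
          cfg$overlap_markers, min(cfg$markers_per_platform))
  }
  if (length(cfg$missing_rate) != 2L || !all(is_rate(cfg$missing_rate))) {
    stopf("sim_config: 'missing_rate' must be two rates in [0, 1]")
  }
  if (length(cfg$geno_error_rate) != 2L || !all(is_rate(cfg$geno_error_rate))) {
    stopf("sim_config: 'geno_error_rate' must be two rates in [0, 1]")
  }
  if (!(length(cfg$recomb_rate) == 1L && is.finite(cfg$recomb_rate) && cfg$recomb_rate >= 0)) {
    stopf("sim_config: 'recomb_rate' must be a non-negative number")
  }
  if (!(length(cfg$seed) == 1L && is.finite(cfg$seed))) {
    stopf("sim_config: 'seed' must be a single integer")
  }
  invisible(cfg)
}

#' Trait architecture for phenotype simulation
#'
#' Defines the genetic and environmental composition of a simulated trait:
#' number of QTL, additive and dominance variances, the directional
#' inbreeding (inbreeding depression) coefficient `b` in phenotype units per
#' unit of inbreeding, calendar-year offsets, and residual variance.
#'
#' The default year effects are a fixed, deliberately unbalanced set of
#' offsets over ten evaluation years, emulating the year-to-year swings of
#' field trials.
#'
#' @param n_qtl Number of causal markers.
#' @param additive_var Variance of the summed additive QTL effects.
#' @param dominance_var Variance of the summed dominance deviations.
#' @param inbreeding_effect_b Fixed regression of phenotype on true genomic
#'   inbreeding F (phenotype units per unit F). Negative values model
#'   inbreeding depression.
#' @param year_effects Named numeric vector mapping calendar year to its
#'   additive offset.
#' @param residual_var Residual (within-year) variance.
#'
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(n_qtl = 30,
                               additive_var = 1,
                               dominance_var = 0.3,
                               inbreeding_effect_b = -2,
                               year_effects = NULL,
                               residual_var = 1) {
  if (is.null(year_effects)) {
    year_effects <- stats::setNames(
      c(0.31, -0.22, 0.05, 0.48, -0.37, 0.12, -0.05, 0.27, -0.41, 0.09),
      as.character(2001:2010)
    )
  }
  arch <- list(
    n_qtl = as.integer(n_qtl),
    additive_var = as.numeric(additive_var),
    dominance_var = as.numeric(dominance_var),
    inbreeding_effect_b = as.numeric(inbreeding_effect_b),
    year_effects = year_effects,
    residual_var = as.numeric(residual_var)
  )
  vars <- c(arch$additive_var, arch$dominance_var, arch$residual_var)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stopf("trait_architecture: variances must be finite and >= 0")
  }
  if (!is_count(arch$n_qtl)) stopf("trait_architecture: 'n_qtl' must be a positive count")
  if (is.null(names(arch$year_effects)) || !is.numeric(arch$year_effects)) {
    stopf("trait_architecture: 'year_effects' must be a named numeric vector (year -> offset)")
  }
  class(arch) <- "trait_architecture"
  arch
}
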