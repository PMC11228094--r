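#' Simulate phenotypes with additive, dominance, inbreeding and year effects
#'
#' Generates phenotype records
#' \deqn{y_{iy} = \mu + g_i^{(a)} + g_i^{(d)} + b F_i + year_y + e_{iy}}
#' where the additive component is a sum of QTL effects scaled to
#' `additive_var`, the dominance component a sum of heterozygote deviations
#' scaled to `dominance_var`, `F_i` is the *true* genomic inbreeding of the
#' individual (identity-by-descent fraction from the simulator's origin
#' paths), `b` the directional inbreeding (inbreeding depression)
#' coefficient, and `year_y` a calendar-year offset. Individuals of the
#' parental population are evaluated in several years, offspring typically in
#' one, giving the unbalanced design typical of breeding programs.
#'
#' @param truth A `truth_set` covering all phenotyped individuals.
#' @param architecture A [trait_architecture()].
#' @param pedigree The pedigree the truth set was dropped on (used to decide
#'   how many evaluation years an individual gets).
#' @param years Calendar years available for evaluation; defaults to the
#'   years named in `architecture$year_effects`.
#' @param seed Integer seed.
#' @return A list of class `phenotype_sim`:
#'   \describe{
#'     \item{phenotypes}{data frame `id`, `trait`, `year`, `value`.}
#'     \item{qtl}{data frame of causal markers and their raw effects.}
#'     \item{genetic_values}{named vector of total genetic values
#'       (additive + dominance), i.e. the simulated breeding-value truth.}
#'     \item{F_true}{named vector of true inbreeding coefficients.}
#'     \item{b}{the inbreeding coefficient used.}
#'   }
#' @export
simulate_phenotypes <- function(truth, architecture, pedigree,
                                years = NULL, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"), inherits(architecture, "trait_architecture"))
  set.seed(seed)
  if (is.null(years)) years <- as.integer(names(architecture$year_effects))
  year_eff <- stats::setNames(rep(0, length(years)), as.character(years))
  known <- intersect(names(architecture$year_effects), names(year_eff))
  year_eff[known] <- architecture$year_effects[known]

  n <- length(truth$ids)
  m <- nrow(truth$map)
  if (architecture$n_qtl > m) {
    stopf("simulate_phenotypes: n_qtl (%d) exceeds the marker count (%d)",
          architecture$n_qtl, m)
  }
  qtl_idx <- sort(sample.int(m, architecture$n_qtl))
  X <- truth$hap$h1[, qtl_idx, drop = FALSE] + truth$hap$h2[, qtl_idx, drop = FALSE]
  H <- (X == 1L) * 1

  scale_to <- function(g, v) {
    if (v == 0) return(rep(0, length(g)))
    s <- stats::var(g)
    if (s < .Machine$double.eps) return(rep(0, length(g)))
    (g - mean(g)) * sqrt(v / s)
  }
  a_raw <- stats::rnorm(architecture$n_qtl)
  d_raw <- stats::rnorm(architecture$n_qtl)
  g_a <- scale_to(as.vector(X %*% a_raw), architecture$additive_var)
  g_d <- scale_to(as.vector(H %*% d_raw), architecture$dominance_var)
  Ftrue <- true_inbreeding(truth)
  gv <- stats::setNames(g_a + g_d, truth$ids)

  role <- if (!is.null(pedigree$role)) pedigree$role[match(truth$ids, pedigree$id)] else rep("parent", n)
  n_years <- ifelse(role == "parent", pmin(3L, length(years)), 1L)

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    yy <- years[sample.int(length(years), n_years[i])]
    e <- stats::rnorm(n_years[i], 0, sqrt(architecture$residual_var))
    recs[[i]] <- data.frame(
      id = truth$ids[i], trait = "T1", year = as.integer(yy),
      value = gv[i] + architecture$inbreeding_effect_b * Ftrue[i] +
        year_eff[as.character(yy)] + e,
      stringsAsFactors = FALSE
    )
  }
  phen <- do.call(rbind, recs)
  rownames(phen) <- NULL

  structure(list(
    phenotypes = phen,
    qtl = data.frame(marker = truth$map$id[qtl_idx], index = qtl_idx,
                     add_effect = a_raw, dom_effect = d_raw,
                     stringsAsFactors = FALSE),
    genetic_values = gv,
    F_true = stats::setNames(Ftrue, truth$ids),
    b = architecture$inbreeding_effect_b,
    year_effects = year_eff
  ), class = "phenotype_sim")
}
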