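#' Evaluate genomic prediction under the Train 1-3 designs
#'
#' Standard training-population comparison for a program part-way through a
#' genotyping-platform switch. The test set is always the dual-genotyped
#' families' offspring; the three training designs are:
#' \describe{
#'   \item{Train 1}{parental population, platform-B markers only.}
#'   \item{Train 2}{parental population, merged markers of both platforms.}
#'   \item{Train 3}{parental population plus all non-test families, merged
#'     markers.}
#' }
#' Accuracy is the Pearson correlation r between predicted and observed
#' test phenotypes (negative estimates are reported as zero) together with
#' the RMSE.
#'
#' @param merged List with `geno` and `map` from [merge_platforms()].
#' @param phenotypes Data frame `id`, `value` of year-adjusted phenotypes
#'   (one record per individual), e.g. from [adjust_year_effects()].
#' @param pedigree Pedigree with `role`, `dual`, `family` columns.
#' @param scenarios Subset of 1:3.
#' @param model GBLUP model label passed to [fit_gblup()].
#' @param F_coeffs Named inbreeding coefficients (needed for F models).
#' @param train_ids,test_ids Optional explicit training/test sets overriding
#'   the pedigree-derived defaults; overlapping sets are rejected.
#' @return Data frame of class `prediction_report`: `scenario`, `model`,
#'   `n_train`, `n_test`, `r` (clamped at 0), `r_raw`, `rmse`.
#' @export
run_train_scenarios <- function(merged, phenotypes, pedigree,
                                scenarios = 1:3, model = "A",
                                F_coeffs = NULL,
                                train_ids = NULL, test_ids = NULL) {
  stopifnot(all(scenarios %in% 1:3))
  phen <- stats::setNames(phenotypes$value, phenotypes$id)
  geno <- merged$geno; map <- merged$map

  if (is.null(test_ids)) {
    test_ids <- pedigree$id[pedigree$role == "offspring" & pedigree$dual]
  }
  test_ids <- intersect(intersect(test_ids, names(phen)), rownames(geno))
  if (!length(test_ids)) stopf("run_train_scenarios: empty test set")

  parents <- pedigree$id[pedigree$role == "parent"]
  other_off <- pedigree$id[pedigree$role == "offspring" & !pedigree$dual]

  out <- vector("list", length(scenarios))
  for (si in seq_along(scenarios)) {
    sc <- scenarios[si]
    tr <- train_ids %||% if (sc == 3) c(parents, other_off) else parents
    tr <- intersect(intersect(tr, names(phen)), rownames(geno))
    if (length(intersect(tr, test_ids))) {
      stopf("run_train_scenarios: training set overlaps the test set")
    }
    markers <- if (sc == 1) map$platform == "B" else rep(TRUE, nrow(map))
    sub <- geno[c(tr, test_ids), markers, drop = FALSE]
    K <- additive_kernel(sub)
    y <- stats::setNames(rep(NA_real_, nrow(sub)), rownames(sub))
    y[tr] <- phen[tr]
    fit <- fit_gblup(y, F_coeffs = F_coeffs, kernels = list(A = K), model = model)
    pred <- fit$predictions[test_ids]
    obs <- phen[test_ids]
    r_raw <- stats::cor(pred, obs)
    out[[si]] <- data.frame(
      scenario = sc, model = model,
      n_train = length(tr), n_test = length(test_ids),
      r = max(r_raw, 0), r_raw = r_raw,
      rmse = sqrt(mean((pred - obs)^2)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  class(res) <- c("prediction_report", "data.frame")
  res
}
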