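#' Fit a GBLUP genomic prediction model
#'
#' REML mixed-model genomic prediction with an additive kernel, optionally a
#' dominance kernel, and optionally the individual inbreeding coefficient as
#' a fixed covariate (directional dominance / inbreeding depression). The
#' four model labels follow the usual naming:
#' \describe{
#'   \item{`"A"`}{additive kernel only.}
#'   \item{`"AF"`}{additive kernel + inbreeding fixed effect.}
#'   \item{`"AD"`}{additive + dominance kernels.}
#'   \item{`"ADF"`}{additive + dominance kernels + inbreeding fixed effect.}
#' }
#' Individuals with missing phenotypes are excluded from the fit but receive
#' BLUPs and predictions through their kernel rows, which is how test-set
#' individuals are predicted.
#'
#' @param y Named phenotype vector over all individuals in the kernels; NA
#'   marks unphenotyped (test) individuals.
#' @param F_coeffs Named inbreeding coefficients (marker-based F_ROH in the
#'   standard pipeline); required for models containing `F`.
#' @param kernels List with `A` (and `D` for dominance models) relationship
#'   matrices sharing dimnames.
#' @param model One of `"A"`, `"AF"`, `"AD"`, `"ADF"`.
#' @return Object of class `gp_fit`: fixed effects `beta` (with the
#'   inbreeding slope `b` when modelled), variance components `vc`,
#'   per-kernel BLUPs, `predictions` for every individual, the training
#'   ids, and the REML log-likelihood.
#' @export
fit_gblup <- function(y, F_coeffs = NULL, kernels, model = c("A", "AF", "AD", "ADF")) {
  model <- match.arg(model)
  KA <- kernels$A
  ids <- rownames(KA)
  if (is.null(ids)) stopf("fit_gblup: kernels need dimnames (individual ids)")
  if (is.null(names(y))) {
    stopifnot(length(y) == length(ids))
    names(y) <- ids
  }
  y <- y[ids]
  use_F <- grepl("F", model)
  use_D <- grepl("D", model)
  if (use_D && is.null(kernels$D)) stopf("fit_gblup: model %s needs a dominance kernel", model)

  train <- ids[!is.na(y)]
  if (length(train) < 3L) stopf("fit_gblup: fewer than 3 phenotyped individuals")
  ti <- match(train, ids)

  X_all <- matrix(1, length(ids), 1L, dimnames = list(ids, "Intercept"))
  if (use_F) {
    if (is.null(F_coeffs)) stopf("fit_gblup: model %s needs F_coeffs", model)
    Fv <- F_coeffs[ids]
    if (stats::sd(Fv[ti]) < 1e-12) {
      warnf("fit_gblup: inbreeding coefficient constant in the training set; dropping the inbreeding term")
      use_F <- FALSE
    } else {
      X_all <- cbind(X_all, F = Fv)
    }
  }
  X_t <- X_all[ti, , drop = FALSE]
  y_t <- as.numeric(y[ti])

  if (!use_D) {
    fit <- fit_null_lmm(y_t, X_t, KA[ti, ti])
    lam <- fit$lambda
    H <- lam * KA[ti, ti] + diag(1, length(ti))
    r <- y_t - X_t %*% fit$beta
    Hinv_r <- solve(H, r)
    u_A <- as.numeric(lam * KA[, ti] %*% Hinv_r)
    u_D <- rep(0, length(ids))
    vc <- c(additive = fit$sigma2_g, dominance = 0, residual = fit$sigma2_e)
    loglik <- fit$loglik
    beta <- fit$beta
  } else {
    fit <- fit_lmm_multikernel(y_t, X_t, list(A = KA[ti, ti], D = kernels$D[ti, ti]))
    lam <- fit$lambdas
    u_A <- as.numeric(lam[1] * KA[, ti] %*% fit$Hinv_r)
    u_D <- as.numeric(lam[2] * kernels$D[, ti] %*% fit$Hinv_r)
    vc <- c(additive = unname(fit$sigma2["A"]),
            dominance = unname(fit$sigma2["D"]),
            residual = unname(fit$sigma2["e"]))
    loglik <- fit$loglik
    beta <- fit$beta
  }
  names(beta) <- colnames(X_t)
  pred <- as.numeric(X_all %*% beta) + u_A + u_D
  names(pred) <- ids

  structure(list(
    model = model, beta = beta,
    b = if (use_F) unname(beta["F"]) else NA_real_,
    vc = vc,
    blup = list(additive = stats::setNames(u_A, ids),
                dominance = stats::setNames(u_D, ids)),
    predictions = pred, train = train, loglik = loglik
  ), class = "gp_fit")
}

#' Improvement rate from adding a model term
#'
#' Ratios comparing two prediction evaluations of the same test set:
#' `r_ratio` = r(with) / r(without) and `rmse_ratio` = RMSE(without) /
#' RMSE(with), so values above 1 mean the added term (typically the
#' inbreeding fixed effect) improved both criteria. A zero baseline
#' correlation leaves `r_ratio` undefined (NA).
#'
#' @param fit_with,fit_without Lists (or one-row data frames) carrying
#'   elements/columns `r` and `rmse`.
#' @return Named vector `r_ratio`, `rmse_ratio`.
#' @export
improvement_rate <- function(fit_with, fit_without) {
  rw <- as.numeric(fit_with[["r"]]); r0 <- as.numeric(fit_without[["r"]])
  mw <- as.numeric(fit_with[["rmse"]]); m0 <- as.numeric(fit_without[["rmse"]])
  c(r_ratio = if (isTRUE(r0 == 0)) NA_real_ else rw / r0,
    rmse_ratio = m0 / mw)
}

#' Project an inbreeding effect onto later generations
#'
#' The expected contribution of an individual's inbreeding effect halves
#' with each additional generation of descent (a child transmits half its
#' genome): effect = child_effect * (1/2)^(generations - 1).
#'
#' @param child_effect Effect size in the first descendant generation.
#' @param generations Generation number (1 = child, 2 = grandchild, ...).
#' @return The projected effect.
#' @export
project_inbreeding_effect <- function(child_effect, generations) {
  if (any(generations < 1) || any(generations != round(generations))) {
    stopf("project_inbreeding_effect: generations must be integers >= 1")
  }
  child_effect * 0.5^(generations - 1)
}
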