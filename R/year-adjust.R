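#' Adjust phenotypes for calendar-year effects
#'
#' Fits, per trait, the additive two-way fixed-effect model
#' `value ~ genotype + year` by least squares and returns one adjusted value
#' per genotype: the genotype's fitted mean at the unweighted average of the
#' year effects (an effects-style adjusted mean, appropriate for the heavily
#' unbalanced year designs of long-running field trials). With a single year
#' the adjusted value is simply the genotype mean.
#'
#' The genotype-by-year incidence design must be connected (the bipartite
#' graph linking genotypes and years through observations has one
#' component); otherwise year and genotype effects are confounded and the
#' function stops, naming the disconnected blocks.
#'
#' @param phenotypes Data frame with columns `id`, `trait`, `year`, `value`.
#' @return Data frame `id`, `trait`, `value` with one adjusted record per
#'   genotype per trait.
#' @export
adjust_year_effects <- function(phenotypes) {
  stopifnot(all(c("id", "trait", "year", "value") %in% names(phenotypes)))
  out <- lapply(split(phenotypes, phenotypes$trait), adjust_one_trait)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @keywords internal
#' @noRd
adjust_one_trait <- function(ph) {
  trait <- ph$trait[1L]
  ids <- unique(ph$id)
  years <- sort(unique(ph$year))
  if (length(years) == 1L) {
    mu <- tapply(ph$value, ph$id, mean)
    return(data.frame(id = names(mu), trait = trait,
                      value = as.numeric(mu), stringsAsFactors = FALSE))
  }
  check_connected(ph)
  id_f <- factor(ph$id, levels = ids)
  yr_f <- factor(ph$year, levels = years)
  fit <- stats::lm(value ~ id_f + yr_f, data = data.frame(value = ph$value, id_f, yr_f))
  cf <- stats::coef(fit)
  g_eff <- c(0, cf[paste0("id_f", ids[-1L])])
  y_eff <- c(0, cf[paste0("yr_f", years[-1L])])
  adj <- unname(cf["(Intercept)"]) + g_eff + mean(y_eff)
  data.frame(id = ids, trait = trait, value = as.numeric(adj),
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
check_connected <- function(ph) {
  ids <- unique(ph$id); years <- unique(ph$year)
  # BFS over the bipartite genotype-year graph
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ycomp <- stats::setNames(rep(NA_integer_, length(years)), as.character(years))
  k <- 0L
  for (start in ids) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      g <- queue[1L]; queue <- queue[-1L]
      yy <- as.character(unique(ph$year[ph$id == g]))
      new_y <- yy[is.na(ycomp[yy])]
      ycomp[new_y] <- k
      for (y in new_y) {
        gg <- unique(ph$id[ph$year == as.integer(y)])
        fresh <- gg[is.na(comp[gg])]
        comp[fresh] <- k
        queue <- c(queue, fresh)
      }
    }
  }
  if (k > 1L) {
    blocks <- split(names(comp), comp)
    msg <- paste(vapply(blocks, function(b)
      paste0("{", paste(utils::head(b, 5), collapse = ","),
             if (length(b) > 5) ",..." else "", "}"), character(1)),
      collapse = " | ")
    stopf("adjust_year_effects: genotype-by-year design is disconnected: %s", msg)
  }
  invisible(TRUE)
}
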