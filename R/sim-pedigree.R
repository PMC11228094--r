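#' Simulate a breeding-program pedigree
#'
#' Builds a pedigree that mimics a long-running clonal crop breeding program:
#' a founder set, a few generations of crosses *within* the parental
#' population (with preferential reuse of a handful of popular parents, which
#' drives inbreeding up over time), and a final layer of full-sib families.
#' Crossing years advance by generation with random jitter, so the year
#' structure is unbalanced as it is in real programs.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `pedigree` with columns `id`, `sire`, `dam`
#'   (NA for founders), `crossing_year`, `registration_year`, `generation`,
#'   `family` (NA for the parental population), `role`
#'   (`"parent"`/`"offspring"`) and `dual` (genotyped on both platforms).
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 6, n_families = 3))
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  n_f <- config$n_founders
  founders <- data.frame(
    id = sprintf("P%03d", seq_len(n_f)),
    sire = NA_character_, dam = NA_character_,
    crossing_year = NA_integer_,
    registration_year = 1955L + sample.int(10L, n_f, replace = TRUE),
    generation = 0L, family = NA_character_,
    role = "parent", dual = TRUE,
    stringsAsFactors = FALSE
  )
  ped <- founders
  # popularity weights: a few leading cultivars are reused heavily
  popularity <- function(ids) {
    w <- 0.5 ^ (seq_along(ids) %% 7L)
    w / sum(w)
  }

  next_id <- n_f
  for (g in seq_len(config$n_parent_generations)) {
    n_new <- max(2L, ceiling(n_f / 2))
    avail <- ped$id[ped$role == "parent"]
    w <- popularity(avail)
    year0 <- 1965L + 12L * g
    for (k in seq_len(n_new)) {
      pr <- sample(avail, 2L, prob = w)  # distinct parents
      next_id <- next_id + 1L
      cy <- year0 + sample.int(8L, 1L) - 1L
      ped <- rbind(ped, data.frame(
        id = sprintf("P%03d", next_id),
        sire = pr[1], dam = pr[2],
        crossing_year = cy, registration_year = cy + 5L,
        generation = g, family = NA_character_,
        role = "parent", dual = TRUE,
        stringsAsFactors = FALSE
      ))
    }
  }

  parents <- ped$id
  gen_fam <- config$n_parent_generations + 1L
  w <- popularity(parents)
  sizes <- sample(seq(config$family_size_range[1], config$family_size_range[2]),
                  config$n_families, replace = TRUE)
  dual_fams <- sort(sample.int(config$n_families, config$n_dual_families))
  off <- vector("list", config$n_families)
  child <- 0L
  for (f in seq_len(config$n_families)) {
    pr <- sample(parents, 2L, prob = w)
    cy <- 1990L + sample.int(25L, 1L) - 1L
    fam_id <- sprintf("F%03d", f)
    ids <- sprintf("C%04d", child + seq_len(sizes[f]))
    child <- child + sizes[f]
    off[[f]] <- data.frame(
      id = ids, sire = pr[1], dam = pr[2],
      crossing_year = cy, registration_year = cy + 5L,
      generation = gen_fam, family = fam_id,
      role = "offspring", dual = f %in% dual_fams,
      stringsAsFactors = FALSE
    )
  }
  ped <- rbind(ped, do.call(rbind, off))
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate and topologically order a pedigree
#'
#' Checks that the pedigree is acyclic and that every named parent exists,
#' and returns it with parents ordered before their offspring.
#'
#' @param ped A data frame with at least columns `id`, `sire`, `dam`.
#' @return The pedigree, topologically sorted.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) {
    stopf("pedigree: duplicated individual ids: %s",
          paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  prt <- c(ped$sire, ped$dam)
  unknown <- setdiff(prt[!is.na(prt)], ped$id)
  if (length(unknown)) {
    stopf("pedigree: unknown parent id(s): %s", paste(unknown, collapse = ", "))
  }
  # Kahn topological sort over the parent -> child DAG
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    cyc <- setdiff(seq_len(n), ord)
    stopf("pedigree: cycle detected involving: %s",
          paste(ped$id[cyc], collapse = " -> "))
  }
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
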