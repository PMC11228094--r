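#' Parameters for consecutive-SNP runs-of-homozygosity detection
#'
#' Defaults follow the consecutive-runs convention used for dense panels in
#' livestock and tree crops: a run needs at least 100 SNPs and 1 Mb of
#' length, tolerates at most one heterozygous and one missing call in total,
#' and is broken by an inter-SNP gap above 1 Mb.
#'
#' @param min_snp Minimum number of SNPs in a run.
#' @param max_gap Maximum gap (bp) between consecutive SNPs inside a run.
#' @param min_length Minimum run length (bp, first to last SNP inclusive).
#' @param max_opp_run Maximum heterozygous calls tolerated per run.
#' @param max_miss_run Maximum missing calls tolerated per run.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snp = 100, max_gap = 1e6, min_length = 1e6,
                       max_opp_run = 1, max_miss_run = 1) {
  p <- list(min_snp = as.integer(min_snp), max_gap = as.numeric(max_gap),
            min_length = as.numeric(min_length),
            max_opp_run = as.integer(max_opp_run),
            max_miss_run = as.integer(max_miss_run))
  if (any(vapply(p, function(x) !is.finite(x) || x < 0, logical(1)))) {
    stopf("roh_params: all parameters must be finite and >= 0")
  }
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity by the consecutive-SNP method
#'
#' Scans each chromosome of each individual for maximal stretches of
#' consecutive SNPs containing at most `max_opp_run` heterozygous and
#' `max_miss_run` missing calls in total, with no inter-SNP gap above
#' `max_gap`; stretches with at least `min_snp` SNPs spanning at least
#' `min_length` bp are reported as runs. Runs never span chromosomes.
#' Every *maximal* qualifying window is emitted (a window is maximal when it
#' cannot be extended in either direction without violating a constraint),
#' so runs may occasionally overlap around an excess heterozygote.
#'
#' @param geno Dosage matrix (individuals x markers) or a single row vector.
#' @param map Marker map (`id`, `chrom`, `pos`), sorted by position within
#'   chromosome (unsorted input is an error).
#' @param params A [roh_params()].
#' @return Data frame with one row per run: `id`, `chrom`, `start`, `end`
#'   (bp of the first/last SNP), `n_snps`, `length` (= end - start + 1).
#' @export
detect_roh <- function(geno, map, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  if (!is.matrix(geno)) {
    geno <- matrix(geno, nrow = 1L, dimnames = list("ind1", NULL))
  }
  stopifnot(ncol(geno) == nrow(map))
  for (cc in unique(map$chrom)) {
    pos <- map$pos[map$chrom == cc]
    if (is.unsorted(pos, strictly = FALSE)) {
      stopf("detect_roh: marker map unsorted on chromosome %s", cc)
    }
  }
  ids <- rownames(geno) %||% paste0("ind", seq_len(nrow(geno)))

  out <- vector("list", 0L)
  for (cc in unique(map$chrom)) {
    ix <- which(map$chrom == cc)
    pos <- map$pos[ix]
    # split at gaps exceeding max_gap: no run may cross them
    gaps <- which(diff(pos) > params$max_gap)
    seg_start <- c(1L, gaps + 1L)
    seg_end <- c(gaps, length(ix))
    for (i in seq_len(nrow(geno))) {
      grow <- geno[i, ix]
      for (s in seq_along(seg_start)) {
        rng <- seg_start[s]:seg_end[s]
        runs <- maximal_windows(grow[rng], params$max_opp_run, params$max_miss_run)
        if (!nrow(runs)) next
        st <- rng[runs$L]; en <- rng[runs$R]
        n_snps <- en - st + 1L
        len <- pos[en] - pos[st] + 1
        ok <- n_snps >= params$min_snp & len >= params$min_length
        if (!any(ok)) next
        out[[length(out) + 1L]] <- data.frame(
          id = ids[i], chrom = cc, start = pos[st][ok], end = pos[en][ok],
          n_snps = n_snps[ok], length = len[ok], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(0), chrom = integer(0),
                      start = numeric(0), end = numeric(0),
                      n_snps = integer(0), length = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# two-pointer enumeration of all maximal windows with bounded heterozygote
# and missing counts; g is a dosage vector (1/0/-1/NA)
#' @keywords internal
#' @noRd
maximal_windows <- function(g, max_het, max_miss) {
  n <- length(g)
  het <- cumsum(c(0L, !is.na(g) & g == 0L))
  mis <- cumsum(c(0L, is.na(g)))
  cnt_het <- function(L, R) het[R + 1L] - het[L]
  cnt_mis <- function(L, R) mis[R + 1L] - mis[L]
  Ls <- integer(0); Rs <- integer(0)
  R <- 0L
  prevR <- 0L
  for (L in seq_len(n)) {
    if (R < L - 1L) R <- L - 1L
    while (R < n && cnt_het(L, R + 1L) <= max_het && cnt_mis(L, R + 1L) <= max_miss) {
      R <- R + 1L
    }
    if (R >= L && (L == 1L || R > prevR)) {
      Ls <- c(Ls, L); Rs <- c(Rs, R)
    }
    prevR <- R
  }
  data.frame(L = Ls, R = Rs)
}

#' Genomic inbreeding coefficient from ROH (F_ROH)
#'
#' Per individual, the summed length of the ROH-covered genome (the union of
#' the individual's run intervals per chromosome, so overlapping maximal
#' windows are not double-counted) divided by the SNP-covered genome length,
#' i.e. the sum over chromosomes of (last SNP position - first SNP position
#' + 1).
#'
#' @param runs Run table from [detect_roh()].
#' @param map The marker map the runs were detected on.
#' @param ids Individuals to report (default: those with runs). Individuals
#'   without runs get F_ROH = 0.
#' @return Named numeric vector of F_ROH values in [0, 1].
#' @export
froh <- function(runs, map, ids = NULL) {
  if (nrow(map) == 0L) stopf("froh: empty marker map")
  denom <- sum(vapply(unique(map$chrom), function(cc) {
    p <- map$pos[map$chrom == cc]
    max(p) - min(p) + 1
  }, numeric(1)))
  if (is.null(ids)) ids <- unique(runs$id)
  f <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(runs)) {
    for (id in intersect(ids, unique(runs$id))) {
      ri <- runs[runs$id == id, , drop = FALSE]
      covered <- 0
      for (cc in unique(ri$chrom)) {
        rc <- ri[ri$chrom == cc, , drop = FALSE]
        o <- order(rc$start)
        st <- rc$start[o]; en <- rc$end[o]
        cur_s <- st[1]; cur_e <- en[1]
        for (k in seq_along(st)[-1]) {
          if (st[k] <= cur_e + 1) {
            cur_e <- max(cur_e, en[k])
          } else {
            covered <- covered + (cur_e - cur_s + 1)
            cur_s <- st[k]; cur_e <- en[k]
          }
        }
        covered <- covered + (cur_e - cur_s + 1)
      }
      f[id] <- covered / denom
    }
  }
  f
}

#' ROH islands from per-SNP run incidence
#'
#' Computes, for every SNP, the percentage of individuals whose ROH cover
#' it, takes the incidence value at the `100 - top_pct` percentile as the
#' island threshold (ties included), and reports the maximal consecutive SNP
#' intervals at or above the threshold, per chromosome.
#'
#' @param runs Run table from [detect_roh()].
#' @param map Marker map.
#' @param ids All individuals analysed (the incidence denominator); defaults
#'   to the individuals appearing in `runs`.
#' @param top_pct Percentage of most-frequent SNPs defining islands
#'   (default 15).
#' @return List of class `roh_island_set`: `incidence` (map + `incidence`
#'   column, in %), `threshold`, `islands` (data frame `chrom`, `start`,
#'   `end`, `n_snps`, `max_incidence`).
#' @export
roh_islands <- function(runs, map, ids = NULL, top_pct = 15) {
  if (is.null(ids)) ids <- unique(runs$id)
  if (!length(ids)) stopf("roh_islands: no individuals")
  inc <- numeric(nrow(map))
  if (nrow(runs)) {
    for (cc in unique(runs$chrom)) {
      ix <- which(map$chrom == cc)
      pos <- map$pos[ix]
      rc <- runs[runs$chrom == cc, , drop = FALSE]
      # count covering individuals per SNP without double-counting an
      # individual whose (overlapping) runs both cover a SNP
      cov <- matrix(FALSE, length(unique(rc$id)), length(ix),
                    dimnames = list(unique(rc$id), NULL))
      for (k in seq_len(nrow(rc))) {
        inside <- pos >= rc$start[k] & pos <= rc$end[k]
        cov[rc$id[k], inside] <- TRUE
      }
      inc[ix] <- colSums(cov)
    }
  }
  inc <- 100 * inc / length(ids)
  threshold <- as.numeric(stats::quantile(inc, 1 - top_pct / 100, type = 7))

  islands <- list()
  for (cc in unique(map$chrom)) {
    ix <- which(map$chrom == cc)
    hot <- inc[ix] >= threshold
    if (!any(hot)) next
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      sel <- ix[starts[k]:ends[k]]
      islands[[length(islands) + 1L]] <- data.frame(
        chrom = cc, start = map$pos[sel[1]], end = map$pos[sel[length(sel)]],
        n_snps = length(sel), max_incidence = max(inc[sel]),
        stringsAsFactors = FALSE
      )
    }
  }
  islands <- if (length(islands)) do.call(rbind, islands) else
    data.frame(chrom = integer(0), start = numeric(0), end = numeric(0),
               n_snps = integer(0), max_incidence = numeric(0))
  rownames(islands) <- NULL
  structure(list(
    incidence = cbind(map, incidence = inc),
    threshold = threshold,
    islands = islands
  ), class = "roh_island_set")
}
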