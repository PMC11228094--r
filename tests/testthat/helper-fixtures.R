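# Shared in-code fixtures for the test suite. Everything is generated at
# test time under fixed seeds; nothing is read from disk.

# a small but structured study: 3 chromosomes, two platforms, 4 families
small_config <- function(seed = 7, ...) {
  sim_config(n_founders = 8, n_parent_generations = 1, n_families = 4,
             n_dual_families = 2, n_chromosomes = 3,
             markers_per_platform = c(120, 110), overlap_markers = 4,
             family_size_range = c(4, 8), seed = seed, ...)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(small_config())
    cache
  }
})

# random unlinked genotype matrix for the model-based tests
random_geno <- function(n, m, seed = 1, freq = stats::runif(m, 0.1, 0.5)) {
  set.seed(seed)
  p <- freq
  g <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)) - 1L, n, m,
              dimnames = list(paste0("i", seq_len(n)), paste0("M", seq_len(m))))
  g
}

# brute-force enumerator of maximal ROH windows: evaluates the window
# definition directly for every left endpoint (per-window counts, no
# incremental state), as the reference for the scanning detect_roh()
brute_force_roh <- function(g, pos, params) {
  n <- length(g)
  hetc <- c(0, cumsum(!is.na(g) & g == 0L))
  misc <- c(0, cumsum(is.na(g)))
  gapc <- c(0, cumsum(c(FALSE, diff(pos) > params$max_gap)))
  window_valid <- function(L, R) {
    hetc[R + 1] - hetc[L] <= params$max_opp_run &&
      misc[R + 1] - misc[L] <= params$max_miss_run &&
      gapc[R + 1] - gapc[L + 1] == 0
  }
  out <- list()
  for (L in seq_len(n)) {
    R <- L:n
    ok <- (hetc[R + 1] - hetc[L]) <= params$max_opp_run &
      (misc[R + 1] - misc[L]) <= params$max_miss_run &
      (gapc[R + 1] - gapc[L + 1]) == 0
    if (!ok[1]) next
    Rmax <- L - 1L + max(which(ok))
    if (L > 1 && window_valid(L - 1L, Rmax)) next   # not left-maximal
    n_snps <- Rmax - L + 1L
    len <- pos[Rmax] - pos[L] + 1
    if (n_snps >= params$min_snp && len >= params$min_length) {
      out[[length(out) + 1L]] <- data.frame(start = pos[L], end = pos[Rmax],
                                            n_snps = n_snps, length = len)
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_snps = integer(0), length = numeric(0)))
  }
  do.call(rbind, out)
}

# Wright path-counting coancestry: an independent recursion used as the
# oracle for the tabular-method pedigree inbreeding
wright_kinship <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  memo <- new.env()
  f <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      s <- si[i]; d <- di[i]
      0.5 * (1 + if (!is.na(s) && !is.na(d)) f(s, d) else 0)
    } else {
      # j is never an ancestor of i when i < j (topological order)
      s <- si[j]; d <- di[j]
      0.5 * ((if (!is.na(s)) f(i, s) else 0) + (if (!is.na(d)) f(i, d) else 0))
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- f(i, j)
  K
}

wright_inbreeding <- function(ped) {
  ped <- validate_pedigree(ped)
  K <- wright_kinship(ped)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  vapply(seq_len(nrow(ped)), function(i) {
    s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
    if (is.na(s) || is.na(d)) 0 else K[s, d]
  }, numeric(1))
}
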