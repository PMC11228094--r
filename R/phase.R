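#' Phase a full-sib family against phased parents
#'
#' For each offspring and chromosome, chooses the pair of parental-haplotype
#' mosaics (one gamete from the dam, one from the sire) that minimises the
#' number of mismatches with the observed offspring genotypes under a
#' per-crossover penalty, by dynamic programming (Viterbi) over the four
#' parental-origin states (dam haplotype 1/2 x sire haplotype 1/2). Missing
#' offspring genotypes carry no emission cost, so the same pass imputes them
#' from the parental alleles along the chosen paths.
#'
#' Markers at which an offspring genotype is Mendelian-impossible given the
#' parents are treated as missing for that offspring; if more than 5% of an
#' offspring's non-missing markers are impossible a warning is raised (the
#' fraction is also returned per offspring).
#'
#' The crossover penalty (default 2.5 mismatch units) is set so that the DP
#' prefers one crossover over three or more isolated mismatches, matching
#' typical genotyping-error versus recombination rates.
#'
#' @param parent_haps List with elements `dam` and `sire`, each a 2 x m
#'   matrix of 0/1 haplotype alleles over the marker map (rows = the
#'   parent's two haplotypes).
#' @param offspring_geno Dosage matrix (offspring x m), entries in
#'   \{1, 0, -1, NA\}.
#' @param marker_map Marker map (`id`, `chrom`, `pos`) for the m markers.
#' @param penalty Per-crossover penalty in mismatch units.
#' @param seed Unused by the DP itself (it is deterministic); accepted so
#'   the family-phasing and origin-voting interfaces match.
#' @return List of class `phased_family`:
#'   \describe{
#'     \item{h1,h2}{phased haplotype matrices (offspring x m); `h1` is the
#'       dam-derived, `h2` the sire-derived haplotype.}
#'     \item{o1,o2}{parental-origin paths: which dam/sire haplotype (1 or 2)
#'       each gamete copies at each marker.}
#'     \item{mendel_frac}{per-offspring fraction of Mendelian-impossible
#'       markers.}
#'     \item{n_conflicts}{per-offspring count of non-missing markers whose
#'       observed genotype disagrees with the reconstructed haplotype sum
#'       (declared genotyping-error positions).}
#'   }
#' @export
phase_family <- function(parent_haps, offspring_geno, marker_map,
                         penalty = 2.5, seed = NULL) {
  dam <- parent_haps$dam; sire <- parent_haps$sire
  m <- nrow(marker_map)
  stopifnot(is.matrix(dam), is.matrix(sire),
            ncol(dam) == m, ncol(sire) == m, nrow(dam) == 2L, nrow(sire) == 2L)
  if (!is.matrix(offspring_geno)) offspring_geno <- matrix(offspring_geno, nrow = 1L)
  stopifnot(ncol(offspring_geno) == m)
  n <- nrow(offspring_geno)

  # Mendelian screen: possible dosages from the four parental combinations
  poss <- rbind(dam[1, ] + sire[1, ], dam[1, ] + sire[2, ],
                dam[2, ] + sire[1, ], dam[2, ] + sire[2, ]) - 1L
  g <- offspring_geno
  impossible <- !is.na(g) &
    !(g == matrix(poss[1, ], n, m, byrow = TRUE) |
      g == matrix(poss[2, ], n, m, byrow = TRUE) |
      g == matrix(poss[3, ], n, m, byrow = TRUE) |
      g == matrix(poss[4, ], n, m, byrow = TRUE))
  n_obs <- rowSums(!is.na(g))
  mendel_frac <- ifelse(n_obs > 0, rowSums(impossible) / n_obs, 0)
  if (any(mendel_frac > 0.05)) {
    warnf("phase_family: %d offspring exceed 5%% Mendelian-impossible markers (max %.1f%%); those markers are treated as missing",
          sum(mendel_frac > 0.05), 100 * max(mendel_frac))
  }
  g[impossible] <- NA_integer_

  # emission costs for the 4 states: 1=(d1,s1) 2=(d1,s2) 3=(d2,s1) 4=(d2,s2)
  E <- vector("list", 4L)
  for (s in 1:4) {
    ds <- c(1L, 1L, 2L, 2L)[s]; ss <- c(1L, 2L, 1L, 2L)[s]
    exp_g <- matrix(poss[(ds - 1L) * 2L + ss, ], n, m, byrow = TRUE)
    E[[s]] <- (!is.na(g) & g != exp_g) * 1
  }

  # transition costs: penalty per gamete switch; tiny bonus for staying put
  sw <- matrix(c(0, 1, 1, 2,
                 1, 0, 2, 1,
                 1, 2, 0, 1,
                 2, 1, 1, 0), 4L, 4L)
  C <- penalty * sw
  diag(C) <- diag(C) - 1e-9

  o1 <- matrix(NA_integer_, n, m, dimnames = dimnames(offspring_geno))
  o2 <- o1
  for (cc in unique(marker_map$chrom)) {
    ix <- which(marker_map$chrom == cc)
    mc <- length(ix)
    M <- cbind(E[[1]][, ix[1]], E[[2]][, ix[1]], E[[3]][, ix[1]], E[[4]][, ix[1]])
    back <- array(1L, dim = c(n, 4L, mc))
    if (mc > 1L) {
      for (j in 2:mc) {
        Mn <- M
        for (sp in 1:4) {
          cand <- M + matrix(C[, sp], n, 4L, byrow = TRUE)
          best <- max.col(-cand, ties.method = "first")
          back[, sp, j] <- best
          Mn[, sp] <- cand[cbind(seq_len(n), best)] + E[[sp]][, ix[j]]
        }
        M <- Mn
      }
    }
    state <- max.col(-M, ties.method = "first")
    for (j in mc:1) {
      o1[, ix[j]] <- c(1L, 1L, 2L, 2L)[state]
      o2[, ix[j]] <- c(1L, 2L, 1L, 2L)[state]
      if (j > 1L) state <- back[cbind(seq_len(n), state, j)]
    }
  }

  h1 <- matrix(dam[cbind(as.vector(o1), rep(seq_len(m), each = n))], n, m)
  h2 <- matrix(sire[cbind(as.vector(o2), rep(seq_len(m), each = n))], n, m)
  dimnames(h1) <- dimnames(h2) <- dimnames(offspring_geno)
  recon <- h1 + h2 - 1L
  n_conflicts <- rowSums(!is.na(g) & recon != g)

  structure(list(h1 = h1, h2 = h2, o1 = o1, o2 = o2,
                 mendel_frac = mendel_frac, n_conflicts = n_conflicts),
            class = "phased_family")
}
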