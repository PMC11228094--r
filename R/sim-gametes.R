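#' Drop gametes through a pedigree
#'
#' Extends a founder truth set to every individual of a pedigree by
#' simulating meiosis: for each gamete and chromosome, the number of
#' crossovers is Poisson with mean `config$recomb_rate`, crossover positions
#' are uniform along the chromosome, and there is no interference. Each
#' non-founder haplotype is therefore a mosaic of its parent's two
#' haplotypes, and the per-marker parental-origin path of every gamete is
#' recorded, together with the founder-haplotype labels that define true
#' autozygosity.
#'
#' @param pedigree A pedigree data frame (`id`, `sire`, `dam`, ...); parents
#'   must precede offspring (see [validate_pedigree()]).
#' @param founder_truth A `truth_set` from [simulate_founders()] covering all
#'   pedigree founders.
#' @param config The [sim_config()] used to create the founders.
#' @return A `truth_set` covering every pedigree individual. `hap$h1` is
#'   always the maternal (dam) gamete and `hap$h2` the paternal (sire)
#'   gamete; `origin$o1`/`origin$o2` give, per marker, which haplotype (1 or
#'   2) of the dam/sire that gamete copies.
#' @export
drop_gametes <- function(pedigree, founder_truth, config) {
  validate_sim_config(config)
  pedigree <- validate_pedigree(pedigree)
  set.seed(config$seed + 3L)

  map <- founder_truth$map
  m <- nrow(map)
  n <- nrow(pedigree)
  ids <- pedigree$id
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(cc) which(map$chrom == cc))
  chrom_pos <- lapply(chrom_idx, function(ix) map$pos[ix])
  L <- config$chrom_length_bp

  h1 <- matrix(NA_integer_, n, m, dimnames = list(ids, map$id))
  h2 <- h1; a1 <- h1; a2 <- h1; o1 <- h1; o2 <- h1

  founder_rows <- match(ids, founder_truth$ids)
  row_of <- stats::setNames(seq_len(n), ids)

  # one gamete from parent row `pi`: returns list(h, a, o)
  make_gamete <- function(pi) {
    o <- integer(m)
    for (k in seq_along(chroms)) {
      ix <- chrom_idx[[k]]
      n_co <- stats::rpois(1L, config$recomb_rate)
      start <- sample.int(2L, 1L)
      if (n_co == 0L) {
        o[ix] <- start
      } else {
        br <- sort(stats::runif(n_co, 0, L))
        seg <- findInterval(chrom_pos[[k]], br)  # crossovers before marker
        o[ix] <- 1L + (start - 1L + seg) %% 2L
      }
    }
    pick1 <- o == 1L
    list(
      h = ifelse(pick1, h1[pi, ], h2[pi, ]),
      a = ifelse(pick1, a1[pi, ], a2[pi, ]),
      o = o
    )
  }

  for (i in seq_len(n)) {
    if (is.na(pedigree$sire[i]) || is.na(pedigree$dam[i])) {
      fr <- founder_rows[i]
      if (is.na(fr)) {
        stopf("drop_gametes: founder '%s' is missing from the founder truth set",
              ids[i])
      }
      h1[i, ] <- founder_truth$hap$h1[fr, ]
      h2[i, ] <- founder_truth$hap$h2[fr, ]
      a1[i, ] <- founder_truth$anc$a1[fr, ]
      a2[i, ] <- founder_truth$anc$a2[fr, ]
    } else {
      dm <- row_of[[pedigree$dam[i]]]
      sr <- row_of[[pedigree$sire[i]]]
      gd <- make_gamete(dm)
      gs <- make_gamete(sr)
      h1[i, ] <- gd$h; a1[i, ] <- gd$a; o1[i, ] <- gd$o
      h2[i, ] <- gs$h; a2[i, ] <- gs$a; o2[i, ] <- gs$o
    }
  }

  structure(list(
    map = map, ids = ids,
    hap = list(h1 = h1, h2 = h2),
    anc = list(a1 = a1, a2 = a2),
    origin = list(o1 = o1, o2 = o2),
    founder_freq = founder_truth$founder_freq
  ), class = "truth_set")
}
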