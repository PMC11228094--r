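#' Simulate founder haplotypes and the merged marker map
#'
#' Draws the marker map shared by both genotyping platforms (positions
#' uniform per chromosome, sorted and unique; platform membership assigned at
#' random with `overlap_markers` markers shared) and founder haplotypes with
#' per-marker allele frequencies drawn uniformly on [0.05, 0.95], so that no
#' marker is expected to be near-monomorphic.
#'
#' Every founder haplotype carries a unique ancestral label per marker, which
#' is propagated through meiosis by [drop_gametes()] and underlies the true
#' (identity-by-descent) inbreeding coefficient of every descendant.
#'
#' @param config A [sim_config()] object.
#' @return A `truth_set` object: list with elements
#'   \describe{
#'     \item{map}{marker map (`id`, `chrom`, `pos`, `platform` in
#'       `"A"`, `"B"`, `"AB"`), sorted by position within chromosome.}
#'     \item{ids}{individual ids (founders only at this stage).}
#'     \item{hap}{list of two 0/1 haplotype matrices `h1`, `h2`
#'       (individuals x markers); `h1` is the maternally inherited gamete
#'       for non-founders.}
#'     \item{anc}{list of two integer matrices of founder-haplotype labels.}
#'     \item{origin}{list of two parental-origin path matrices (which
#'       haplotype, 1 or 2, of the dam/sire each gamete copies; NA for
#'       founders).}
#'     \item{founder_freq}{the allele frequencies the founders were drawn at.}
#'   }
#' @examples
#' ts <- simulate_founders(sim_config(n_founders = 2, n_chromosomes = 1,
#'                                    markers_per_platform = c(6, 6),
#'                                    overlap_markers = 2))
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)

  m_total <- sum(config$markers_per_platform) - config$overlap_markers
  nc <- config$n_chromosomes
  # distribute markers over chromosomes as evenly as possible
  per_chrom <- rep(m_total %/% nc, nc)
  extra <- m_total %% nc
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  maps <- vector("list", nc)
  for (cc in seq_len(nc)) {
    pos <- sort(sample.int(config$chrom_length_bp, per_chrom[cc]))
    maps[[cc]] <- data.frame(chrom = cc, pos = pos)
  }
  map <- do.call(rbind, maps)
  map$id <- sprintf("M%05d", seq_len(nrow(map)))
  # platform membership: overlap markers on both, the rest split A/B
  plat <- rep(NA_character_, m_total)
  shuffled <- sample.int(m_total)
  n_ab <- config$overlap_markers
  n_a_only <- config$markers_per_platform[1] - n_ab
  plat[shuffled[seq_len(n_ab)]] <- "AB"
  plat[shuffled[n_ab + seq_len(n_a_only)]] <- "A"
  plat[is.na(plat)] <- "B"
  map$platform <- plat
  map <- map[, c("id", "chrom", "pos", "platform")]

  n <- config$n_founders
  freq <- stats::runif(m_total, 0.05, 0.95)
  h1 <- matrix(stats::rbinom(n * m_total, 1L, rep(freq, each = n)), n, m_total)
  h2 <- matrix(stats::rbinom(n * m_total, 1L, rep(freq, each = n)), n, m_total)
  ids <- sprintf("P%03d", seq_len(n))
  dimnames(h1) <- dimnames(h2) <- list(ids, map$id)
  a1 <- matrix(rep(2L * seq_len(n) - 1L, m_total), n, m_total, dimnames = dimnames(h1))
  a2 <- a1 + 1L
  o1 <- matrix(NA_integer_, n, m_total, dimnames = dimnames(h1))

  structure(list(
    map = map, ids = ids,
    hap = list(h1 = h1, h2 = h2),
    anc = list(a1 = a1, a2 = a2),
    origin = list(o1 = o1, o2 = o1),
    founder_freq = freq
  ), class = "truth_set")
}

#' True dosage genotypes of a truth set
#'
#' Sum of the two haplotypes, recoded to the dosage scale used throughout the
#' package: 1 = AA, 0 = Aa, -1 = aa.
#'
#' @param truth A `truth_set`.
#' @return Integer matrix (individuals x markers) with entries in
#'   \{1, 0, -1\}.
#' @export
true_dosage <- function(truth) {
  truth$hap$h1 + truth$hap$h2 - 1L
}

#' True genomic inbreeding from identity-by-descent
#'
#' Fraction of markers at which the two haplotypes of an individual descend
#' from the same founder haplotype (autozygosity), computed from the
#' ancestral labels the simulator propagates through every meiosis.
#'
#' @param truth A `truth_set`.
#' @return Named numeric vector of true inbreeding coefficients in [0, 1].
#' @export
true_inbreeding <- function(truth) {
  rowMeans(truth$anc$a1 == truth$anc$a2)
}
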