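# A pedigree with the population sizes of a large apple breeding program:
# 184 parents; 15 dual-platform families totalling 191 F1; 192 further
# families totalling 2,032 F1 genotyped on platform A only.
reference_scale_pedigree <- function() {
  parents <- data.frame(
    id = sprintf("P%03d", 1:184), sire = NA_character_, dam = NA_character_,
    crossing_year = NA_integer_, registration_year = 1960L,
    generation = 0L, family = NA_character_, role = "parent", dual = TRUE,
    stringsAsFactors = FALSE
  )
  sizes <- c(rep(13L, 11), rep(12L, 4),      # 15 dual families, 191 F1
             rep(11L, 112), rep(10L, 80))    # 192 more families, 2032 F1
  dual <- rep(c(TRUE, FALSE), c(15L, 192L))
  set.seed(99)
  off <- vector("list", length(sizes))
  k <- 0L
  for (f in seq_along(sizes)) {
    pr <- sample(parents$id[1:61], 2L)
    off[[f]] <- data.frame(
      id = sprintf("C%04d", k + seq_len(sizes[f])),
      sire = pr[1], dam = pr[2],
      crossing_year = 2000L, registration_year = 2005L,
      generation = 1L, family = sprintf("F%03d", f),
      role = "offspring", dual = dual[f], stringsAsFactors = FALSE
    )
    k <- k + sizes[f]
  }
  rbind(parents, do.call(rbind, off))
}
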