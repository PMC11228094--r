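# one-chromosome map helper
flat_map <- function(m, chrom = 1L, spacing = 1000L) {
  data.frame(id = sprintf("M%03d", seq_len(m)), chrom = chrom,
             pos = seq_len(m) * spacing)
}

test_that("fully homozygous distinct parents force the phase", {
  m <- 40
  map <- flat_map(m)
  dam <- rbind(rep(1L, m), rep(1L, m))   # AA everywhere
  sire <- rbind(rep(0L, m), rep(0L, m))  # aa everywhere
  off <- matrix(0L, 2, m)                # all heterozygous, as it must be
  ph <- phase_family(list(dam = dam, sire = sire), off, map)
  expect_true(all(ph$h1 == 1L))
  expect_true(all(ph$h2 == 0L))
  expect_equal(unname(ph$n_conflicts), c(0L, 0L))
})

test_that("without recombination the inferred origin paths have no breakpoints", {
  set.seed(10)
  m <- 60
  map <- flat_map(m)
  dam <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  sire <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  off <- matrix((dam[1, ] + sire[2, ]) - 1L, 1, m)  # d1 x s2, no crossover
  ph <- phase_family(list(dam = dam, sire = sire), off, map)
  expect_equal(length(unique(ph$o1[1, ])), 1L)
  expect_equal(length(unique(ph$o2[1, ])), 1L)
})

test_that("a single simulated crossover is localised within one marker interval", {
  set.seed(11)
  m <- 100
  map <- flat_map(m)
  dam <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  sire <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  bp <- 57L  # maternal gamete switches from dam hap 1 to hap 2 after marker 57
  o1_true <- c(rep(1L, bp), rep(2L, m - bp))
  h1 <- dam[cbind(o1_true, 1:m)]
  h2 <- sire[1, ]
  off <- matrix(h1 + h2 - 1L, 1, m)
  ph <- phase_family(list(dam = dam, sire = sire), off, map)
  # exhaustive oracle: mismatch cost of every single-breakpoint maternal mosaic
  costs <- vapply(0:m, function(b) {
    o <- c(rep(1L, b), rep(2L, m - b))
    sum(dam[cbind(o, 1:m)] != h1)
  }, numeric(1))
  minimisers <- which(costs == min(costs)) - 1L
  inferred_bp <- which(diff(ph$o1[1, ]) != 0)
  expect_equal(length(inferred_bp), 1L)
  expect_true(bp %in% minimisers)
  expect_true(inferred_bp[1] %in% minimisers)
  # truth and DP may disagree only within one uninformative marker interval
  informative <- which(dam[1, ] != dam[2, ])
  lo <- max(informative[informative <= bp])
  hi <- min(informative[informative > bp])
  expect_gte(inferred_bp[1], lo)
  expect_lt(inferred_bp[1], hi)
  # the paternal gamete carries no crossover
  expect_equal(length(unique(ph$o2[1, ])), 1L)
})

test_that("Mendelian-impossible markers trigger a warning and are ignored", {
  m <- 60
  map <- flat_map(m)
  dam <- rbind(rep(1L, m), rep(1L, m))
  sire <- rbind(rep(1L, m), rep(1L, m))
  off <- matrix(1L, 1, m)
  off[1, 1:5] <- -1L  # impossible: both parents AA
  expect_warning(ph <- phase_family(list(dam = dam, sire = sire), off, map),
                 "Mendelian")
  expect_gt(ph$mendel_frac[1], 0.05)
  expect_true(all(ph$h1 == 1L))
})

test_that("estimated haplotypes sum to observed genotypes except declared errors", {
  sim <- small_sim()
  ped <- sim$pedigree
  merged <- merge_platforms(sim$geno$A, sim$maps$A, sim$geno$B, sim$maps$B)
  fam <- ped[!is.na(ped$family) & ped$family == "F001", ]
  tr <- match(c(fam$dam[1], fam$sire[1]), sim$truth$ids)
  cix <- match(merged$map$id, sim$truth$map$id)
  parent_haps <- list(
    dam = rbind(sim$truth$hap$h1[tr[1], cix], sim$truth$hap$h2[tr[1], cix]),
    sire = rbind(sim$truth$hap$h1[tr[2], cix], sim$truth$hap$h2[tr[2], cix])
  )
  off_geno <- merged$geno[intersect(fam$id, rownames(merged$geno)), , drop = FALSE]
  ph <- phase_family(parent_haps, off_geno, merged$map)
  recon <- ph$h1 + ph$h2 - 1L
  mism <- sum(!is.na(off_geno) & recon != off_geno)
  expect_equal(mism, sum(ph$n_conflicts))   # every disagreement is declared
  expect_lt(mism / sum(!is.na(off_geno)), 0.05)
})

test_that("window voting labels a copied haplotype with a unanimous vote", {
  set.seed(12)
  m <- 120
  map <- flat_map(m)
  dam <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  sire <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  res <- estimate_parental_origin(dam[1, ], list(dam = dam, sire = sire), map,
                                  n_markers = 30, reps = 100, seed = 1)
  expect_equal(res$label, "female")
  expect_equal(unname(res$votes["female"]), 100L)

  res2 <- estimate_parental_origin(sire[2, ], list(dam = dam, sire = sire), map,
                                   n_markers = 30, reps = 100, seed = 1)
  expect_equal(res2$label, "male")
})

test_that("window voting on unrelated noise matches the full-enumeration majority", {
  set.seed(13)
  m <- 150
  map <- flat_map(m)
  dam <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  sire <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  noise <- rbinom(m, 1, 0.5)
  # oracle: enumerate every window start instead of sampling
  haps <- rbind(dam, sire)
  votes <- c(female = 0L, male = 0L)
  for (st in 1:(m - 29)) {
    w <- st:(st + 29)
    x <- noise[w]
    if (stats::sd(x) == 0) next
    r <- apply(haps[, w], 1, function(h) if (stats::sd(h) == 0) NA else cor(x, h))
    best <- which.max(r)
    lab <- if (best <= 2) "female" else "male"
    votes[lab] <- votes[lab] + 1L
  }
  oracle_label <- names(which.max(votes))
  res <- estimate_parental_origin(noise, list(dam = dam, sire = sire), map,
                                  n_markers = 30, reps = 2000, seed = 2)
  share <- res$votes["female"] / sum(res$votes)
  expect_gt(share, 0.3)  # vote split near 50/50, not unanimous
  expect_lt(share, 0.7)
  expect_equal(res$label, oracle_label)
})

test_that("voting is unknown when no polymorphic window can be drawn", {
  m <- 60
  map <- flat_map(m)
  set.seed(14)
  dam <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  sire <- rbind(rbinom(m, 1, 0.5), rbinom(m, 1, 0.5))
  res <- estimate_parental_origin(rep(1L, m), list(dam = dam, sire = sire),
                                  map, n_markers = 30, reps = 100, seed = 3)
  expect_equal(res$label, "unknown")
  expect_equal(res$n_valid, 0L)
  expect_error(estimate_parental_origin(dam[1, ], list(dam = dam, sire = sire),
                                        map, n_markers = 100),
               "no chromosome")
})

test_that("imputation from origin paths reconstructs masked cells", {
  m <- 50
  map <- flat_map(m)
  set.seed(15)
  dam <- rbind(rep(1L, m), rep(1L, m))
  sire <- rbind(rep(0L, m), rep(0L, m))
  off <- matrix(0L, 3, m)
  ph <- phase_family(list(dam = dam, sire = sire), off, map)
  mask <- matrix(FALSE, 3, m); mask[, 11:20] <- TRUE
  imp <- impute_from_origin(ph, list(dam = dam, sire = sire), mask)
  expect_true(all(imp$geno[mask] == 0L))     # Aa offspring, predictable by hand
  expect_true(all(is.na(imp$geno[!mask])))
  expect_equal(imp$n_unimputed, 0L)

  # empty mask leaves nothing imputed
  imp0 <- impute_from_origin(ph, list(dam = dam, sire = sire),
                             matrix(FALSE, 3, m))
  expect_true(all(is.na(imp0$geno)))
})

test_that("score and phasing accuracy match hand counts", {
  imputed <- matrix(c(1L, 0L, -1L, NA), 2, 2)
  truth <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  expect_equal(score_accuracy(imputed, truth, mask), 0.5)
  expect_equal(score_accuracy(truth, truth, mask), 1)
  expect_equal(score_accuracy(matrix(NA_integer_, 2, 2), truth, mask), 0)
  # 3 of 4 masked cells correct
  imp2 <- truth; imp2[2, 2] <- -1L
  expect_equal(score_accuracy(imp2, truth, mask), 0.75)

  th1 <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  tg <- matrix(0L, 2, 2)  # heterozygous everywhere
  perfect <- phasing_accuracy(th1, th1, tg)
  expect_equal(perfect$accuracy, 1)
  swapped <- phasing_accuracy(1L - th1, th1, tg)
  expect_equal(swapped$accuracy, 0)
})

test_that("imputation accuracy degrades as the scaffold missing rate rises", {
  # dataset 2 recovers platform-A cells from the platform-B scaffold, so
  # raising platform-B missingness starves the origin inference directly
  accs_b <- vapply(c(0.0, 0.15, 0.4), function(mr) {
    cfg <- small_config(missing_rate = c(0.005, mr), seed = 31)
    sim <- simulate_study(cfg)
    evaluate_imputation(sim, 2)$score_accuracy
  }, numeric(1))
  expect_gte(accs_b[1], accs_b[2])
  expect_gte(accs_b[2], accs_b[3])
})
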