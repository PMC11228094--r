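test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_founders = 0), "positive count")
  expect_error(sim_config(missing_rate = c(0.5, 1.5)), "rates")
  expect_error(sim_config(markers_per_platform = c(10, 10), overlap_markers = 11),
               "exceeds the smaller panel")
  expect_error(sim_config(family_size_range = c(5, 2)), "family_size_range")
})

test_that("founder simulation has the right shape and is seed-reproducible", {
  cfg <- sim_config(n_founders = 2, n_chromosomes = 1,
                    markers_per_platform = c(6, 6), overlap_markers = 2)
  ts <- simulate_founders(cfg)
  expect_equal(dim(ts$hap$h1), c(2, 10))
  expect_equal(dim(ts$hap$h2), c(2, 10))
  expect_true(all(ts$hap$h1 %in% 0:1) && all(ts$hap$h2 %in% 0:1))
  expect_false(is.unsorted(ts$map$pos[ts$map$chrom == 1]))
  expect_false(anyDuplicated(ts$map$pos[ts$map$chrom == 1]) > 0)
  ts2 <- simulate_founders(cfg)
  expect_identical(ts$hap, ts2$hap)
  expect_identical(ts$map, ts2$map)
})

test_that("founder allele frequencies respect the MAF floor", {
  cfg <- sim_config(n_founders = 2000, n_chromosomes = 2,
                    markers_per_platform = c(120, 100), overlap_markers = 20,
                    seed = 11)
  ts <- simulate_founders(cfg)
  p_hat <- colMeans(rbind(ts$hap$h1, ts$hap$h2))
  # with p >= 0.05, a binomial 99.9% lower bound over 4000 draws stays above
  # 0.05 - 3.3 * sqrt(p(1-p)/4000); check every marker against its own bound
  n_hap <- 2 * cfg$n_founders
  lower <- 0.05 - 3.29 * sqrt(ts$founder_freq * (1 - ts$founder_freq) / n_hap)
  upper <- 0.95 + 3.29 * sqrt(ts$founder_freq * (1 - ts$founder_freq) / n_hap)
  expect_true(all(p_hat >= pmax(lower, 0)))
  expect_true(all(p_hat <= pmin(upper, 1)))
})

test_that("gamete dropping without recombination copies whole parental chromosomes", {
  cfg <- small_config(recomb_rate = 0)
  ped <- simulate_pedigree(cfg)
  truth <- drop_gametes(ped, simulate_founders(cfg), cfg)
  off <- ped$id[!is.na(ped$sire)][1]
  i <- match(off, truth$ids)
  for (cc in unique(truth$map$chrom)) {
    ix <- truth$map$chrom == cc
    expect_equal(length(unique(truth$origin$o1[i, ix])), 1L)
    dm <- match(ped$dam[match(off, ped$id)], truth$ids)
    o <- truth$origin$o1[i, which(ix)[1]]
    parent_hap <- if (o == 1L) truth$hap$h1[dm, ix] else truth$hap$h2[dm, ix]
    expect_identical(truth$hap$h1[i, ix], parent_hap)
  }
})

test_that("haplotypes always sum to the genotype and selfing halves heterozygosity", {
  sim <- small_sim()
  expect_true(all(true_dosage(sim$truth) ==
                    sim$truth$hap$h1 + sim$truth$hap$h2 - 1L))

  # many selfed offspring of one individual
  cfg <- small_config(seed = 3)
  founders <- simulate_founders(cfg)
  ped <- data.frame(id = c("P001", sprintf("S%03d", 1:300)),
                    sire = c(NA, rep("P001", 300)),
                    dam = c(NA, rep("P001", 300)))
  truth <- drop_gametes(ped, founders, cfg)
  g <- true_dosage(truth)
  het_parent <- mean(g["P001", ] == 0L)
  het_off <- mean(g[-1, ] == 0L)
  expect_equal(het_off, het_parent / 2, tolerance = 0.05)
})

test_that("unknown parent ids are reported by name", {
  cfg <- small_config()
  ped <- data.frame(id = c("P001", "X"), sire = c(NA, "GHOST"), dam = c(NA, "P001"))
  expect_error(drop_gametes(ped, simulate_founders(cfg), cfg), "GHOST")
})

test_that("phenotypes reduce to their deterministic parts in degenerate settings", {
  sim <- small_sim()
  arch0 <- trait_architecture(n_qtl = 5, additive_var = 0, dominance_var = 0,
                              inbreeding_effect_b = 0,
                              year_effects = c(`2005` = 0), residual_var = 0)
  ph <- simulate_phenotypes(sim$truth, arch0, sim$pedigree, seed = 4)
  expect_equal(stats::var(ph$phenotypes$value), 0)

  archb <- trait_architecture(n_qtl = 5, additive_var = 0, dominance_var = 0,
                              inbreeding_effect_b = -2,
                              year_effects = c(`2005` = 0), residual_var = 0)
  phb <- simulate_phenotypes(sim$truth, archb, sim$pedigree, seed = 4)
  v <- tapply(phb$phenotypes$value, phb$phenotypes$id, mean)
  f <- phb$F_true[names(v)]
  # phenotype differences equal -2 times the inbreeding differences
  expect_equal(as.numeric(v - v[which.min(f)]),
               as.numeric(-2 * (f - min(f))), tolerance = 1e-12)
})

test_that("OLS on true inbreeding recovers b within its standard error", {
  cfg <- sim_config(n_founders = 10, n_parent_generations = 3, n_families = 30,
                    n_dual_families = 5, n_chromosomes = 5,
                    markers_per_platform = c(150, 140), overlap_markers = 5,
                    family_size_range = c(12, 20), seed = 21)
  ped <- simulate_pedigree(cfg)
  truth <- drop_gametes(ped, simulate_founders(cfg), cfg)
  arch <- trait_architecture(n_qtl = 10, additive_var = 0, dominance_var = 0,
                             inbreeding_effect_b = -2,
                             year_effects = c(`2005` = 0), residual_var = 1)
  ph <- simulate_phenotypes(truth, arch, ped, seed = 5)
  y <- tapply(ph$phenotypes$value, ph$phenotypes$id, mean)
  f <- ph$F_true[names(y)]
  fit <- summary(stats::lm(y ~ f))
  expect_gt(length(y), 400)
  expect_lt(abs(fit$coefficients["f", "Estimate"] - (-2)),
            3 * fit$coefficients["f", "Std. Error"])
})

test_that("platform observation codes, misses and stays consistent on overlaps", {
  cfg <- small_config(missing_rate = c(0, 0))
  sim0 <- simulate_study(cfg)
  expect_false(anyNA(sim0$geno$A))
  expect_true(all(sim0$geno$A %in% c(-1L, 0L, 1L)))

  # shared markers agree between platforms when nothing is missing
  shared <- intersect(sim0$maps$A$id, sim0$maps$B$id)
  expect_equal(length(shared), cfg$overlap_markers)
  ids <- rownames(sim0$geno$B)
  expect_identical(sim0$geno$A[ids, shared], sim0$geno$B[, shared])

  # empirical missing rate within a binomial interval
  cfg2 <- small_config(missing_rate = c(0.016, 0.1), seed = 12)
  sim2 <- simulate_study(cfg2)
  n_cells <- length(sim2$geno$A)
  p_hat <- mean(is.na(sim2$geno$A))
  expect_lt(abs(p_hat - 0.016), 3.3 * sqrt(0.016 * 0.984 / n_cells))
})

test_that("offspring of full sibs have pedigree F of 0.25 on simulated pedigrees", {
  # founder-only parental population, so family parents are unrelated
  ped <- simulate_pedigree(
    sim_config(n_founders = 8, n_parent_generations = 0, n_families = 4,
               n_dual_families = 2, n_chromosomes = 3,
               markers_per_platform = c(120, 110), overlap_markers = 4,
               family_size_range = c(4, 8), seed = 7))
  fam <- ped[!is.na(ped$family) & ped$family == "F001", ]
  extra <- data.frame(id = "FS_CHILD", sire = fam$id[1], dam = fam$id[2],
                      crossing_year = 2020L, registration_year = 2025L,
                      generation = max(ped$generation) + 1L,
                      family = "FX", role = "offspring", dual = FALSE)
  ped2 <- rbind(as.data.frame(ped), extra)
  pf <- pedigree_inbreeding(ped2)
  expect_equal(pf$F_pedigree[pf$id == "FS_CHILD"], 0.25)
})
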