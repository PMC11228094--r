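make_panel <- function(ids, map, geno_fun = NULL, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(c(-1L, 0L, 1L), length(ids) * nrow(map), TRUE),
              length(ids), nrow(map), dimnames = list(ids, map$id))
  g
}

test_that("merging unions markers by position and reports overlaps", {
  mapA <- data.frame(id = paste0("A", 1:5), chrom = 1L,
                     pos = c(10L, 30L, 50L, 70L, 90L), platform = "A")
  mapB <- data.frame(id = paste0("B", 1:4), chrom = 1L,
                     pos = c(20L, 30L, 60L, 90L), platform = "B")
  ids <- paste0("i", 1:20)
  gA <- make_panel(ids, mapA, seed = 1)
  gB <- make_panel(ids, mapB, seed = 2)
  gB[1, 1] <- NA  # platform B has the higher missing rate -> its copies drop
  res <- merge_platforms(gA, mapA, gB, mapB)
  expect_equal(nrow(res$map), 5 + 4 - 2)
  expect_equal(res$overlap$n, 2L)
  expect_setequal(res$overlap$dropped, c("B2", "B4"))
  expect_false(is.unsorted(res$map$pos))
  # retained data equals its source platform
  expect_identical(res$geno[ids, "A2"], gA[, "A2"])
  expect_identical(res$geno[ids, "B3"], gB[, "B3"])
  # consistency equals a brute-force per-cell comparison
  brute <- mean(sapply(list(c("A2", "B2"), c("A5", "B4")), function(pr) {
    a <- gA[, pr[1]]; b <- gB[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    sum(a[ok] == b[ok]) / sum(ok)
  }))
  expect_equal(res$overlap$mean_consistency, brute)
})

test_that("two identical single-marker panels collapse to one consistent marker", {
  map1 <- data.frame(id = "A1", chrom = 1L, pos = 100L, platform = "A")
  map2 <- data.frame(id = "B1", chrom = 1L, pos = 100L, platform = "B")
  g <- matrix(c(1L, 0L, -1L), 3, 1, dimnames = list(paste0("i", 1:3), "A1"))
  g2 <- g; colnames(g2) <- "B1"
  res <- merge_platforms(g, map1, g2, map2)
  expect_equal(nrow(res$map), 1L)
  expect_equal(res$overlap$mean_consistency, 1)
})

test_that("engineered discordance is reflected in the consistency report", {
  set.seed(42)
  map <- data.frame(id = paste0("M", 1:9), chrom = rep(1:3, each = 3),
                    pos = rep(c(100L, 200L, 300L), 3))
  mapA <- transform(map, id = paste0("A", 1:9), platform = "A")
  mapB <- transform(map, id = paste0("B", 1:9), platform = "B")
  ids <- paste0("i", 1:50)
  gA <- make_panel(ids, mapA, seed = 3)
  gB <- gA; colnames(gB) <- mapB$id
  flip <- cbind(sample(50, 9), 1:9)  # one discordant call per marker (2%)
  gB[flip] <- ((gB[flip] + 2L) %% 3L) - 1L
  res <- merge_platforms(gA, mapA, gB, mapB)
  expect_equal(res$overlap$n, 9L)
  expect_equal(res$overlap$mean_consistency, 49 / 50)
})

test_that("individuals genotyped on one platform get missing for the other's markers", {
  mapA <- data.frame(id = "A1", chrom = 1L, pos = 10L, platform = "A")
  mapB <- data.frame(id = "B1", chrom = 1L, pos = 20L, platform = "B")
  gA <- matrix(1L, 2, 1, dimnames = list(c("x", "y"), "A1"))
  gB <- matrix(0L, 1, 1, dimnames = list("z", "B1"))
  res <- merge_platforms(gA, mapA, gB, mapB)
  expect_true(all(is.na(res$geno[c("x", "y"), "B1"])))
  expect_true(all(is.na(res$geno["z", "A1"])))
})

test_that("merging with an empty panel is the identity", {
  sim <- small_sim()
  m1 <- merge_platforms(sim$geno$A, sim$maps$A, sim$geno$B, sim$maps$B)
  empty_map <- sim$maps$B[0, ]
  empty_geno <- sim$geno$B[, 0, drop = FALSE]
  m2 <- merge_platforms(m1$geno, m1$map, empty_geno, empty_map)
  expect_identical(m2$geno, m1$geno)
  expect_equal(m2$map[, c("chrom", "pos")], m1$map[, c("chrom", "pos")])
})

test_that("disjoint chromosome naming is rejected with the unmatched names", {
  mapA <- data.frame(id = "A1", chrom = "chr1", pos = 10L, platform = "A")
  mapB <- data.frame(id = "B1", chrom = "1", pos = 20L, platform = "B")
  gA <- matrix(1L, 1, 1, dimnames = list("x", "A1"))
  gB <- matrix(0L, 1, 1, dimnames = list("x", "B1"))
  expect_error(merge_platforms(gA, mapA, gB, mapB), "chr1")
})

test_that("masking schemes mask exactly their cells and reconcile counts", {
  sim <- small_sim()
  merged <- merge_platforms(sim$geno$A, sim$maps$A, sim$geno$B, sim$maps$B)
  ids <- dataset_individuals(sim$pedigree, 1)
  geno <- merged$geno[intersect(rownames(merged$geno), ids), ]

  sch0 <- mask_scheme(0, character(0), character(0))
  expect_identical(unname(build_masked_dataset(geno, sch0, merged$map)[, ]),
                   unname(geno))

  sch1 <- dataset_scheme(sim$pedigree, 1)
  masked <- build_masked_dataset(geno, sch1, merged$map)
  bcols <- merged$map$platform == "B"
  dual_off <- sch1$cells$id
  expect_true(all(is.na(masked[dual_off, bcols])))
  expect_identical(masked[, !bcols], geno[, !bcols])
  # non-missing cell counting reconciles with the scheme block sizes
  expect_equal(sum(!is.na(geno)) - sum(!is.na(masked)), attr(masked, "n_masked"))
  expect_equal(attr(masked, "n_masked") + attr(masked, "n_prev_missing"),
               length(dual_off) * sum(bcols))
})

test_that("MAF filtering removes rare and monomorphic markers", {
  map <- data.frame(id = paste0("M", 1:3), chrom = 1L, pos = c(1L, 2L, 3L))
  g <- cbind(M1 = c(0L, rep(1L, 99)),          # 1 het in 100: MAF 0.005
             M2 = rep(1L, 100),                # monomorphic
             M3 = sample(c(-1L, 0L, 1L), 100, TRUE))
  rownames(g) <- paste0("i", 1:100)
  out <- filter_maf(g, map, 0.025)
  expect_identical(out$map$id, "M3")
  expect_setequal(out$removed, c("M1", "M2"))
  ident <- filter_maf(g, map, 0)
  expect_identical(ident$geno, g)
  expect_error(filter_maf(g[, 2, drop = FALSE], map[2, ], 0.1), "all markers")
})

test_that("year adjustment matches closed-form least squares and is equivariant", {
  # single year: adjusted value is the genotype mean
  ph1 <- data.frame(id = rep(c("a", "b"), each = 2), trait = "T1",
                    year = 2005L, value = c(1, 3, 10, 14))
  adj1 <- adjust_year_effects(ph1)
  expect_equal(adj1$value[match(c("a", "b"), adj1$id)], c(2, 12))

  # balanced 2x2 with a +1 year offset: de-offset genotype means
  ph2 <- data.frame(id = rep(c("a", "b"), 2), trait = "T1",
                    year = rep(c(2001L, 2002L), each = 2),
                    value = c(5, 7, 5 + 1, 7 + 1))
  adj2 <- adjust_year_effects(ph2)
  expect_equal(adj2$value[match(c("a", "b"), adj2$id)], c(5.5, 7.5))

  # adding a constant shifts every adjusted value by that constant
  ph3 <- ph2; ph3$value <- ph3$value + 100
  adj3 <- adjust_year_effects(ph3)
  expect_equal(adj3$value, adj2$value + 100)
})

test_that("year adjustment preserves ranking under truly additive year effects", {
  set.seed(8)
  ids <- paste0("g", 1:30)
  g_eff <- stats::setNames(sort(rnorm(30)), ids)
  years <- 2001:2004
  y_eff <- stats::setNames(c(2, -1, 0.5, -3), years)
  recs <- do.call(rbind, lapply(ids, function(g) {
    yy <- sample(years, sample(2:4, 1))
    data.frame(id = g, trait = "T1", year = yy,
               value = g_eff[g] + y_eff[as.character(yy)])
  }))
  adj <- adjust_year_effects(recs)
  expect_identical(order(adj$value[match(ids, adj$id)]), order(g_eff))
})

test_that("disconnected genotype-by-year designs are rejected with block names", {
  ph <- data.frame(id = c("a", "a", "b", "b"), trait = "T1",
                   year = c(2001L, 2001L, 2002L, 2002L), value = 1:4)
  expect_error(adjust_year_effects(ph), "disconnected")
})
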