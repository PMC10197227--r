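# Diversity statistics: hand enumerations and rarefaction properties.

test_that("observed heterozygosity matches hand counts on a toy matrix", {
  d <- rbind(c(1L, 0L, 2L),
             c(1L, 1L, NA),
             c(1L, 0L, 0L),
             c(1L, 2L, 0L))
  g <- make_geno(d, sprintf("i%d", 1:4))
  map <- pop_map(data.frame(individual = sprintf("i%d", 1:4),
                            population = "p1", region = "r1",
                            range = "native"))
  ho <- observed_heterozygosity(g, map, "r1", polymorphic_only = FALSE)
  # locus 1: 4/4 het; locus 2: 1/4; locus 3: 0/3 (one missing)
  expect_equal(unname(ho$per_locus), c(1, 0.25, 0))
  expect_equal(ho$mean, mean(c(1, 0.25, 0)))
  # monomorphic locus 3 is dropped from the polymorphic-only mean?
  # locus 3 has alleles 2 and 0 -> polymorphic; all three loci kept
  ho2 <- observed_heterozygosity(g, map, "r1")
  expect_equal(ho2$mean, mean(c(1, 0.25, 0)))
})

test_that("expected heterozygosity follows 2p(1-p)", {
  d <- rbind(c(1L, 0L), c(1L, 0L))        # locus 1: p = 0.5; locus 2: p = 0
  g <- make_geno(d, c("i1", "i2"))
  map <- pop_map(data.frame(individual = c("i1", "i2"), population = "p1",
                            region = "r1", range = "native"))
  he <- expected_heterozygosity(g, map, "r1", polymorphic_only = FALSE)
  expect_equal(unname(he$per_locus), c(0.5, 0))
  # unbiased variant scales by 2n/(2n-1)
  heu <- expected_heterozygosity(g, map, "r1", polymorphic_only = FALSE,
                                 unbiased = TRUE)
  expect_equal(unname(heu$per_locus)[1], 0.5 * 4 / 3)
})

test_that("inbreeding coefficient reproduces limiting cases and toys", {
  ids <- sprintf("i%d", 1:4)
  map <- pop_map(data.frame(individual = ids, population = "p1",
                            region = "r1", range = "native"))
  # all heterozygotes at p = 0.5: Fis = 1 - 1/0.5 = -1
  g_het <- make_geno(matrix(1L, 4, 3), ids)
  expect_equal(inbreeding_coefficient(g_het, map, "r1"), -1)
  # toy: ratio of sums over polymorphic loci, against brute force
  d <- rbind(c(0L, 1L), c(2L, 1L), c(0L, 0L), c(2L, 1L))
  g <- make_geno(d, ids)
  p <- colMeans(d) / 2
  ho <- colMeans(d == 1L)
  he <- 2 * p * (1 - p)
  expect_equal(inbreeding_coefficient(g, map, "r1"),
               1 - sum(ho) / sum(he))
  # monomorphic everywhere -> NA with warning
  g_mono <- make_geno(matrix(0L, 4, 2), ids)
  expect_warning(fis <- inbreeding_coefficient(g_mono, map, "r1"),
                 "monomorphic")
  expect_true(is.na(fis))
})

test_that("rarefied allelic richness matches the exhaustive oracle", {
  ids <- sprintf("i%d", 1:4)
  map <- pop_map(data.frame(individual = ids, population = "p1",
                            region = "r1", range = "native"))
  # N = 4 diploids, allele counts (6, 2): dosages summing to 2 alt of 8
  d <- matrix(c(1L, 1L, 0L, 0L), 4, 1)
  g <- make_geno(d, ids)
  for (gr in c(2, 4, 6)) {
    ar <- allelic_richness(g, map, "r1", g_rarefaction = gr)
    expect_equal(unname(ar$per_locus), enum_ar(c(6, 2), gr),
                 tolerance = 1e-12)
  }
  # rarefying to the full allele count returns the distinct-allele count
  ar_full <- allelic_richness(g, map, "r1", g_rarefaction = 8)
  expect_equal(unname(ar_full$per_locus), 2)
  # monomorphic locus is 1 for any g
  g_mono <- make_geno(matrix(2L, 4, 1), ids)
  expect_equal(unname(allelic_richness(g_mono, map, "r1",
                                       g_rarefaction = 4)$per_locus), 1)
})

test_that("allelic richness is non-decreasing in the rarefaction size", {
  set.seed(8)
  sim <- simulate_genotypes(geno_sim_config(
    n_units = 2, pops_per_unit = 1, inds_per_pop = 12, n_loci = 100,
    missing_rate = 0.05, seed = 8))
  ars <- vapply(c(4, 8, 12, 16), function(gr) {
    allelic_richness(sim$genotypes, sim$map, "region01",
                     g_rarefaction = gr)$mean
  }, numeric(1))
  expect_true(all(diff(ars) >= -1e-12))
})

test_that("diversity table covers every region with sane ranges", {
  sim <- simulate_genotypes(geno_sim_config(
    n_units = 3, pops_per_unit = 2, inds_per_pop = 6, n_loci = 150,
    missing_rate = 0.05, seed = 13))
  tab <- diversity_table(sim$genotypes, sim$map)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$Ho >= 0 & tab$Ho <= 1))
  expect_true(all(tab$He >= 0 & tab$He <= 1))
  expect_true(all(tab$Ar >= 1 & tab$Ar <= 2))
  expect_equal(tab$N, rep(12L, 3))
})

test_that("statistics ignore an all-missing individual", {
  set.seed(14)
  d <- matrix(sample(0:2, 40, replace = TRUE), 8, 5)
  ids <- sprintf("i%d", 1:9)
  d2 <- rbind(d, NA)
  map <- pop_map(data.frame(individual = ids,
                            population = rep(c("p1", "p2"), c(5, 4)),
                            region = rep(c("r1", "r2"), c(5, 4)),
                            range = rep(c("native", "non-native"), c(5, 4))))
  map8 <- pop_map(as.data.frame(map)[1:8, ])
  g8 <- make_geno(d, ids[1:8]); g9 <- make_geno(d2, ids)
  expect_equal(observed_heterozygosity(g8, map8, "r1")$mean,
               observed_heterozygosity(g9, map, "r1")$mean)
  expect_equal(wc_theta(g8, map8)$theta, wc_theta(g9, map)$theta)
})
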