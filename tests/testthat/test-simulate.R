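# Synthetic-data generator: Balding-Nichols moments, determinism, truth
# bookkeeping.

test_that("Balding-Nichols frequencies have the right moments", {
  set.seed(11)
  # near-zero drift: draws collapse onto the ancestral frequency
  f0 <- simulate_subpopulation_frequencies(0.5, 1e-6, 50)
  expect_true(all(abs(f0 - 0.5) < 0.01))
  # closed-form Beta moments: mean p, variance F p (1 - p)
  set.seed(12)
  f <- simulate_subpopulation_frequencies(0.3, 0.1, 60000)
  expect_equal(mean(f), 0.3, tolerance = 0.01)
  expect_equal(stats::var(f), 0.1 * 0.3 * 0.7, tolerance = 0.03)
  expect_true(all(f >= 0 & f <= 1))
  # invalid drift parameter
  expect_error(simulate_subpopulation_frequencies(0.3, 0, 5),
               class = "pstfst_invalid_parameter")
  expect_error(simulate_subpopulation_frequencies(0.3, 1, 5),
               class = "pstfst_invalid_parameter")
})

test_that("seeded genotype simulation is bit-reproducible", {
  cfg <- geno_sim_config(n_units = 3, pops_per_unit = 2, inds_per_pop = 4,
                         n_loci = 50, seed = 7)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$map, s2$map)
})

test_that("genotype simulator honours config switches", {
  s <- simulate_genotypes(geno_sim_config(
    n_units = 2, pops_per_unit = 2, inds_per_pop = 5, n_loci = 40,
    selected_fraction = 0, missing_rate = 0, seed = 3))
  expect_length(s$truth$selected_loci, 0)
  expect_false(anyNA(s$genotypes$dosage))
  expect_equal(dim(s$genotypes$dosage), c(2 * 2 * 5, 40))
  s2 <- simulate_genotypes(geno_sim_config(
    n_units = 2, pops_per_unit = 1, inds_per_pop = 10, n_loci = 200,
    selected_fraction = 0.1, F_neutral = 0.02, F_selected = 0.3,
    missing_rate = 0.3, seed = 4))
  expect_length(s2$truth$selected_loci, 20)
  expect_gt(mean(is.na(s2$genotypes$dosage)), 0.2)
  expect_error(geno_sim_config(F_neutral = 0.2, F_selected = 0.1),
               class = "pstfst_invalid_parameter")
})

test_that("simulated heterozygosity matches the drift-shrunk closed form", {
  # E[2 p_i (1 - p_i)] = 2 p (1 - p) (1 - F) under Balding-Nichols
  cfg <- geno_sim_config(n_units = 4, pops_per_unit = 1, inds_per_pop = 30,
                         n_loci = 10000, ancestral_maf_range = c(0.3, 0.3),
                         F_neutral = 0.1, F_pop = 0, missing_rate = 0,
                         seed = 21)
  s <- simulate_genotypes(cfg)
  he <- expected_heterozygosity(s$genotypes, s$map, "region01",
                                polymorphic_only = FALSE)
  expect_equal(he$mean, 2 * 0.3 * 0.7 * (1 - 0.1), tolerance = 0.02)
})

test_that("trait simulator records exact truth and the right structure", {
  map <- make_map2(sprintf("i%02d", 1:20))
  # direct substitutions into the Pst formula
  t1 <- simulate_traits(map, trait_sim_config(0, 0.5, 1, seed = 1))
  expect_identical(t1$truth$true_pst, 0)
  t2 <- simulate_traits(map, trait_sim_config(1, 0, 1, seed = 1))
  expect_equal(t2$truth$true_pst, 1 / 3)
  t3 <- simulate_traits(map, trait_sim_config(1, 0.5, 1, seed = 1))
  expect_equal(t3$truth$true_pst, 0.25)
  expect_equal(nrow(t3$traits), 20)
  expect_setequal(t3$traits$individual, map$individual)
  # with no between-unit variance the unit effects are exactly zero-var
  expect_true(all(t1$truth$unit_effects == 0))
  # decomposition reproduces the data: y - mu - a - b - e == 0
  recon <- t3$truth$config$grand_mean +
    t3$truth$unit_effects[map$region] +
    t3$truth$pop_effects[map$population]
  expect_true(stats::sd(t3$traits$value - recon) > 0)  # residuals present
})

test_that("pst_formula matches hand substitutions", {
  expect_equal(pst_formula(1, 1, 1), 1 / 3)
  expect_equal(pst_formula(1, 1.5, 1), 0.25)
  expect_equal(pst_formula(0, 2, 1), 0)
  expect_equal(pst_formula(1, 1, 0.5), 0.5)
  expect_equal(pst_formula(0, 0, 1), 0)
})
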