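# Pst inference: sampler determinism, transforms, classification rule.

fake_posterior <- function(draws, cfg = pst_config()) {
  structure(list(draws = draws, chains = list(draws), rhat = c(
    mu = 1, sigma2_B = 1, sigma2_P = 1, sigma2_e = 1),
    n_obs = 10, unit_level = "region", units = c("A", "B"),
    trait = "t", cfg = cfg), class = "pst_posterior")
}

test_that("pst transform matches hand substitutions per draw", {
  draws <- cbind(mu = c(0, 0), sigma2_B = c(1, 0), sigma2_P = c(0, 0.5),
                 sigma2_e = c(1, 1))
  po <- fake_posterior(draws, pst_config(sigma_w_convention = "residual-only"))
  tr <- pst_transform(po)
  expect_equal(unname(tr$draws[, "pst"]), c(1 / 3, 0))
  po2 <- fake_posterior(draws)   # residual-plus-population convention
  tr2 <- pst_transform(po2)
  expect_equal(unname(tr2$draws[, "pst"]), c(1 / 3, 0))
  draws3 <- cbind(mu = 0, sigma2_B = 1, sigma2_P = 0.5, sigma2_e = 1)
  expect_equal(unname(pst_transform(fake_posterior(draws3))$draws[, "pst"]),
               0.25)
})

test_that("classification follows the interval sign rule", {
  expect_equal(classify_divergence(0.16, 0.30), "divergent")
  expect_equal(classify_divergence(-0.02, 0.007), "drift-consistent")
  expect_equal(classify_divergence(-0.30, -0.10), "stabilizing")
  expect_error(classify_divergence(0.3, 0.1))
})

test_that("gibbs_fit is bit-reproducible under a fixed seed", {
  map <- make_map2(sprintf("i%02d", 1:24))
  tr <- simulate_traits(map, trait_sim_config(0.5, 0.3, 1, seed = 61))
  cfg <- pst_config(n_chains = 2, n_iter = 1000, n_burnin = 100, seed = 62)
  f1 <- gibbs_fit(tr$traits, map, cfg)
  f2 <- gibbs_fit(tr$traits, map, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- gibbs_fit(tr$traits, map, pst_config(n_chains = 2, n_iter = 1000,
                                             n_burnin = 100, seed = 63))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("degenerate constant traits do not break the sampler", {
  map <- make_map2(sprintf("i%02d", 1:20))
  traits <- trait_table(data.frame(individual = map$individual,
                                   trait = "flat", value = 5), map)
  expect_warning(
    fit <- gibbs_fit(traits, map, pst_config(n_chains = 2, n_iter = 1000,
                                             n_burnin = 100, seed = 64)),
    "identical")
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(fit$draws[, -1] > 0))
})

test_that("pst draws live in [0, 1] and rhat is near 1 on a healthy fit", {
  map <- pop_map(data.frame(
    individual = sprintf("i%03d", 1:120),
    population = rep(sprintf("p%d", 1:6), each = 20),
    region = rep(c("A", "B"), each = 60),
    range = rep(c("native", "non-native"), each = 60)))
  tr <- simulate_traits(map, trait_sim_config(1, 0.5, 1, seed = 65))
  fit <- pst_transform(gibbs_fit(tr$traits, map,
    pst_config(n_chains = 3, n_iter = 2000, n_burnin = 300, seed = 66)))
  expect_true(all(fit$draws[, "pst"] >= 0 & fit$draws[, "pst"] <= 1))
  expect_true(all(fit$rhat[c("sigma2_B", "sigma2_P", "sigma2_e")] < 1.1))
})

test_that("pst is invariant under affine transformation of the trait", {
  map <- pop_map(data.frame(
    individual = sprintf("i%03d", 1:120),
    population = rep(sprintf("p%d", 1:6), each = 20),
    region = rep(c("A", "B"), each = 60),
    range = rep(c("native", "non-native"), each = 60)))
  tr <- simulate_traits(map, trait_sim_config(1, 0.5, 1, seed = 67))
  cfg <- pst_config(n_chains = 2, n_iter = 2000, n_burnin = 300, seed = 68)
  f1 <- pst_transform(gibbs_fit(tr$traits, map, cfg))
  tr2 <- tr$traits; tr2$value <- 7 * tr2$value - 100
  f2 <- pst_transform(gibbs_fit(tr2, map, cfg))
  expect_equal(mean(f1$draws[, "pst"]), mean(f2$draws[, "pst"]),
               tolerance = 0.02)
})

test_that("posterior mean pst increases with simulated between-unit variance", {
  map <- pop_map(data.frame(
    individual = sprintf("i%03d", 1:120),
    population = rep(sprintf("p%d", 1:6), each = 20),
    region = rep(c("A", "B"), each = 60),
    range = rep(c("native", "non-native"), each = 60)))
  cfg <- pst_config(n_chains = 2, n_iter = 1500, n_burnin = 300, seed = 69)
  means <- vapply(c(0.05, 1, 8), function(s2b) {
    tr <- simulate_traits(map, trait_sim_config(s2b, 0.5, 1, seed = 70))
    mean(pst_transform(gibbs_fit(tr$traits, map, cfg))$draws[, "pst"])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("pst_fst_compare validates fst and supports draw vectors", {
  draws <- cbind(mu = 0, sigma2_B = rep(1, 200), sigma2_P = 0.5,
                 sigma2_e = 1)
  po <- fake_posterior(draws)
  expect_error(pst_fst_compare(po, 1.2), class = "pstfst_invalid_parameter")
  expect_error(pst_fst_compare(po, -0.1), class = "pstfst_invalid_parameter")
  cmp_scalar <- pst_fst_compare(po, 0.05)
  expect_equal(cmp_scalar$diff$mean, 0.25 - 0.05, tolerance = 1e-12)
  expect_equal(cmp_scalar$classification, "divergent")
  cmp_vec <- pst_fst_compare(po, c(0.04, 0.05, 0.06), seed = 3)
  expect_equal(cmp_vec$fst_mean, 0.05)
  expect_equal(cmp_vec$diff$mean, 0.2, tolerance = 0.01)
})

test_that("run_all_comparisons produces the full comparison grid", {
  sim <- simulate_genotypes(geno_sim_config(
    n_units = 3, pops_per_unit = 2, inds_per_pop = 8, n_loci = 200,
    F_neutral = 0.05, seed = 71))
  t1 <- simulate_traits(sim$map, trait_sim_config(
    0.5, 0.3, 1, trait_name = "tA", seed = 72))
  t2 <- simulate_traits(sim$map, trait_sim_config(
    0.5, 0.3, 1, trait_name = "tB", seed = 73))
  traits <- trait_table(rbind(t1$traits, t2$traits), sim$map)
  fst_tab <- fst_comparison_table(sim$genotypes, sim$map,
                                  bootstrap_reps = 0, seed = 2)
  cfg <- pst_config(n_chains = 2, n_iter = 1000, n_burnin = 200, seed = 74)
  res <- run_all_comparisons(traits, sim$map, fst_tab, cfg,
                             comparisons = c("range", "pairwise"))
  # 2 traits x (1 range + choose(3,2) pairwise) rows
  expect_equal(nrow(res), 2 * (1 + 3))
  expect_setequal(unique(res$trait), c("tA", "tB"))
  expect_true(all(res$classification %in%
                    c("divergent", "stabilizing", "drift-consistent")))
  # missing comparison is a named error
  expect_error(
    run_all_comparisons(traits, sim$map, fst_tab[fst_tab$level != "range", ],
                        cfg, comparisons = "range"),
    class = "pstfst_invalid_input")
})
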