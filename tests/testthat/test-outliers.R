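# Outlier scans and the consensus/neutral-set bookkeeping.

test_that("uncorrected per-locus Fst matches direct formula evaluation", {
  d <- rbind(c(2L, 1L, 0L),
             c(2L, 0L, NA),
             c(0L, 1L, 1L),
             c(0L, 2L, 1L))
  ids <- sprintf("i%d", 1:4)
  g <- make_geno(d, ids)
  map <- make_map2(ids)
  res <- per_locus_fst_uncorrected(g, map)
  # brute-force evaluation of s2 / (pbar (1 - pbar)) per locus
  pops <- map$region
  for (l in 1:3) {
    dl <- d[, l]; keep <- !is.na(dl)
    n_i <- tapply(keep, pops, sum)
    p_i <- tapply(dl, pops, function(x) sum(x, na.rm = TRUE)) / (2 * n_i)
    r <- 2; nbar <- mean(n_i)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    expected <- if (pbar <= 0 || pbar >= 1) NA_real_ else
      s2 / (pbar * (1 - pbar))
    expect_equal(unname(res$fst[l]), expected, tolerance = 1e-12)
  }
  # fixation between the groups pushes the statistic to its ceiling
  expect_gt(res$fst[1], 0.9)
})

test_that("trimmed fit rejects degenerate statistic vectors", {
  expect_error(trimmed_chi2_scan(rep(0.1, 100)),
               class = "pstfst_fit_error")
  expect_warning(
    trimmed_chi2_scan(stats::rchisq(30, 5) / 50, df_init = 5),
    "fewer than 50")
})

test_that("trimmed fit recovers the chi-square shape on clean draws", {
  set.seed(51)
  fbar <- 0.06; k <- 5
  x <- fbar * stats::rchisq(5000, k) / k
  fit <- trimmed_chi2_scan(x, df_init = 3)
  expect_equal(fit$fbar, fbar, tolerance = 0.05)
  expect_equal(fit$df, k, tolerance = 1)
  expect_lte(mean(fit$flag, na.rm = TRUE), 0.01)
})

test_that("heterozygosity floor excludes loci from fit and calls", {
  set.seed(52)
  x <- 0.05 * stats::rchisq(500, 5) / 5
  he <- rep(c(0.05, 0.3), length.out = 500)
  fit <- trimmed_chi2_scan(x, he, he_min = 0.10)
  expect_true(all(is.na(fit$q[he < 0.10])))
  expect_true(all(!is.na(fit$q[he >= 0.10])))
})

test_that("pc scan validates K and excludes constant loci", {
  sim <- simulate_genotypes(geno_sim_config(
    n_units = 3, pops_per_unit = 1, inds_per_pop = 8, n_loci = 60,
    seed = 53))
  expect_error(pc_regression_scan(sim$genotypes, 0),
               class = "pstfst_invalid_parameter")
  expect_error(pc_regression_scan(sim$genotypes, 24),
               class = "pstfst_invalid_parameter")
  g2 <- sim$genotypes
  g2$dosage[, 1] <- 1L   # constant locus
  res <- pc_regression_scan(g2, 2)
  expect_true(is.na(res$q[1]))
  expect_length(res$singular_values, min(dim(g2$dosage)))
})

test_that("external scan import merges, validates and warns", {
  ids <- sprintf("L%03d", 1:20)
  path <- file.path(tempdir(), "ext.tsv")
  df <- data.frame(id = ids[c(2, 5, 9, 15)], value = c(0.99, 0.98, 0.97, 1),
                   flag = 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ext <- import_external_scan(path, ids, "bayes")
  expect_equal(sum(ext$flag), 4)
  expect_true(all(ext$flag[c(2, 5, 9, 15)]))
  # unmatched ids are an error naming them
  bad <- df; bad$id[1] <- "nope"
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(import_external_scan(path, ids), "nope",
               class = "pstfst_io_error")
  # empty file: zero flags with a warning
  utils::write.table(df[0, ], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_warning(ext0 <- import_external_scan(path, ids), "empty")
  expect_equal(sum(ext0$flag), 0)
})

test_that("consensus rules partition loci and reproduce the any-rule arithmetic", {
  # 2138 loci of which 163 flagged by at least one method mirrors the
  # 2138 - 163 = 1975 neutral-set arithmetic
  n <- 2138
  report <- data.frame(id = sprintf("L%04d", 1:n),
                       m1_flag = FALSE, m2_flag = FALSE, m3_flag = FALSE)
  report$m1_flag[1:22] <- TRUE                 # 22 from method 1
  report$m2_flag[20:140] <- TRUE               # overlap of 3 with method 1
  report$m3_flag[138:163] <- TRUE              # overlap of 3 with method 2
  cons <- consensus_and_neutral_set(report, rule = "any")
  expect_length(cons$consensus, 163)
  expect_length(cons$neutral_set, n - 163)
  expect_setequal(c(cons$consensus, cons$neutral_set), report$id)
  # tier bookkeeping
  expect_equal(sum(cons$tiers == "two-methods"), 6)
  expect_equal(sum(cons$tiers == "none"), n - 163)
  # stricter rules are nested
  cons2 <- consensus_and_neutral_set(report, rule = "at-least-2")
  cons3 <- consensus_and_neutral_set(report, rule = "all")
  expect_true(all(cons3$consensus %in% cons2$consensus))
  expect_true(all(cons2$consensus %in% cons$consensus))
  expect_length(cons3$consensus, 0)            # no locus hit by all three
  # nothing flagged -> everything neutral
  none <- report; none$m1_flag <- none$m2_flag <- none$m3_flag <- FALSE
  expect_length(consensus_and_neutral_set(none)$consensus, 0)
})

test_that("removing flagged loci does not raise multi-locus theta", {
  sim <- simulate_genotypes(geno_sim_config(
    n_units = 6, pops_per_unit = 1, inds_per_pop = 24, n_loci = 600,
    F_neutral = 0.05, F_selected = 0.5, selected_fraction = 0.05,
    missing_rate = 0.02, seed = 54))
  report <- scan_outliers(sim$genotypes, sim$map)
  cons <- consensus_and_neutral_set(report)
  g_neutral <- subset_geno_for_test(
    sim$genotypes, match(cons$neutral_set, sim$genotypes$locus_meta$id))
  expect_lte(wc_theta(g_neutral, sim$map)$theta,
             wc_theta(sim$genotypes, sim$map)$theta + 1e-10)
})
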