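# Weir-Cockerham F-statistics for diploid biallelic loci.

#' Per-locus Weir-Cockerham variance components
#'
#' Computes, for every locus, the among-population (`a`), among-individual-
#' within-population (`b`) and within-individual (`c`) variance components
#' of the Weir-Cockerham (1984) estimator from genotype counts with unequal
#' and locus-varying sample sizes. Loci at which any group has no genotyped
#' individual, or at which the mean sample size is 1, get `NA` components.
#'
#' @param g A [geno_matrix()].
#' @param groups Character or factor vector assigning each individual (row
#'   of the dosage matrix) to a group.
#' @return List of numeric vectors `a`, `b`, `c` (one entry per locus) plus
#'   `n_groups`.
#' @export
wc_components <- function(g, groups) {
  groups <- as.factor(groups)
  r <- nlevels(groups)
  if (r < 2) {
    stop_pstfst("at least two groups are required", "pstfst_invalid_input")
  }
  d <- g$dosage
  L <- ncol(d)
  n <- matrix(0, r, L); p <- matrix(NA_real_, r, L); h <- matrix(0, r, L)
  for (i in seq_len(r)) {
    di <- d[groups == levels(groups)[i], , drop = FALSE]
    n[i, ] <- colSums(!is.na(di))
    p[i, ] <- ifelse(n[i, ] > 0, colSums(di, na.rm = TRUE) / (2 * n[i, ]), NA)
    h[i, ] <- ifelse(n[i, ] > 0, colSums(di == 1L, na.rm = TRUE) / n[i, ], NA)
  }
  usable <- colSums(n > 0) == r
  nbar <- colSums(n) / r
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  ok <- usable & nbar > 1 & nc > 0
  a <- b <- cc <- rep(NA_real_, L)
  aa <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  bb <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  a[ok] <- aa[ok]; b[ok] <- bb[ok]; cc[ok] <- (hbar / 2)[ok]
  list(a = a, b = b, c = cc, n_groups = r)
}

#' Multi-locus Weir-Cockerham theta
#'
#' Ratio-of-sums estimator `theta = sum(a) / sum(a + b + c)` over loci with
#' a positive total variance.
#'
#' @param g A [geno_matrix()].
#' @param map A [pop_map()].
#' @param units Optional subset of group labels to include; default all.
#' @param level Grouping level treated as the "population" of the model.
#' @return List with `theta`, `per_locus` (per-locus ratios `a/(a+b+c)`,
#'   `NA` where undefined), `n_loci_used`, and the raw `components`.
#' @export
wc_theta <- function(g, map, units = NULL, level = "region") {
  labels <- map_level(map, g$sample_ids, level)
  if (!is.null(units)) {
    keep <- labels %in% units
    g <- subset_geno(g, individuals = which(keep))
    labels <- labels[keep]
  }
  comp <- wc_components(g, labels)
  tot <- comp$a + comp$b + comp$c
  use <- is.finite(tot) & tot > 0
  if (sum(use) < 1) {
    stop_pstfst("no loci with positive total variance", "pstfst_invalid_input")
  }
  list(
    theta = sum(comp$a[use]) / sum(tot[use]),
    per_locus = ifelse(use, comp$a / tot, NA_real_),
    n_loci_used = sum(use),
    components = comp
  )
}

#' Pairwise Weir-Cockerham Fst with a bootstrap confidence interval
#'
#' Treats the two requested groups as the two populations of the
#' Weir-Cockerham model, computes the multi-locus ratio-of-sums theta, and
#' attaches a percentile bootstrap interval obtained by resampling loci.
#'
#' @param g A [geno_matrix()].
#' @param map A [pop_map()].
#' @param unit_a,unit_b Labels of the two groups to compare.
#' @param level Grouping level of the labels.
#' @param bootstrap_reps Number of bootstrap resamples of loci (default
#'   1000); 0 skips the interval.
#' @param conf Bootstrap interval mass (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `fst_result`: list with `unit_a`, `unit_b`,
#'   `theta`, `ci_low`, `ci_high`, `per_locus_theta`, `n_loci_used`.
#' @export
wc_fst <- function(g, map, unit_a, unit_b, level = "region",
                   bootstrap_reps = 1000L, conf = 0.95, seed = 1L) {
  labels <- map_level(map, g$sample_ids, level)
  for (u in c(unit_a, unit_b)) {
    if (sum(labels == u) < 2) {
      stop_pstfst(sprintf("group '%s' has fewer than 2 individuals", u),
                  "pstfst_invalid_input")
    }
  }
  th <- wc_theta(g, map, units = c(unit_a, unit_b), level = level)
  a <- th$components$a; tot <- th$components$a + th$components$b +
    th$components$c
  use <- which(is.finite(tot) & tot > 0)
  if (length(use) < 2) {
    stop_pstfst("fewer than 2 usable loci; bootstrap interval impossible",
                "pstfst_invalid_input")
  }
  ci <- c(NA_real_, NA_real_)
  if (bootstrap_reps > 0) {
    set.seed(seed)
    av <- a[use]; tv <- tot[use]; m <- length(use)
    boots <- vapply(seq_len(bootstrap_reps), function(i) {
      idx <- sample.int(m, m, replace = TRUE)
      sum(av[idx]) / sum(tv[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(boots, interval_probs(conf), names = FALSE))
  }
  structure(list(
    unit_a = unit_a, unit_b = unit_b,
    theta = th$theta, ci_low = ci[1], ci_high = ci[2],
    per_locus_theta = th$per_locus, n_loci_used = length(use)
  ), class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %s vs %s: theta = %.4f (%.4f-%.4f), %d loci\n",
              x$unit_a, x$unit_b, x$theta, x$ci_low, x$ci_high,
              x$n_loci_used))
  invisible(x)
}

#' All pairwise (and range-level) Fst values for the Pst stage
#'
#' Computes the mean multi-locus theta for every pair of regions and for the
#' native versus non-native range split; usually run on the neutral locus
#' set so that the resulting values reflect drift alone.
#'
#' @param g A [geno_matrix()] (typically already restricted to neutral loci).
#' @param map A [pop_map()].
#' @param bootstrap_reps Bootstrap replicates per comparison (default 1000).
#' @param seed Integer seed.
#' @return Data frame with columns `level` (`"region"` or `"range"`),
#'   `unit_a`, `unit_b`, `fst`, `ci_low`, `ci_high`, `n_loci_used`.
#' @export
fst_comparison_table <- function(g, map, bootstrap_reps = 1000L, seed = 1L) {
  regions <- unique(map$region)
  out <- list()
  seeds <- derive_seeds(seed, choose(length(regions), 2) + 1, stream = 3L)
  k <- 0L
  if (length(regions) >= 2) {
    for (i in seq_len(length(regions) - 1)) {
      for (j in seq((i + 1), length(regions))) {
        k <- k + 1L
        f <- wc_fst(g, map, regions[i], regions[j], level = "region",
                    bootstrap_reps = bootstrap_reps, seed = seeds[k])
        out[[length(out) + 1L]] <- data.frame(
          level = "region", unit_a = regions[i], unit_b = regions[j],
          fst = f$theta, ci_low = f$ci_low, ci_high = f$ci_high,
          n_loci_used = f$n_loci_used, stringsAsFactors = FALSE)
      }
    }
  }
  ranges <- unique(map$range)
  if (length(ranges) == 2) {
    f <- wc_fst(g, map, ranges[1], ranges[2], level = "range",
                bootstrap_reps = bootstrap_reps, seed = seeds[k + 1L])
    out[[length(out) + 1L]] <- data.frame(
      level = "range", unit_a = ranges[1], unit_b = ranges[2],
      fst = f$theta, ci_low = f$ci_low, ci_high = f$ci_high,
      n_loci_used = f$n_loci_used, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
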