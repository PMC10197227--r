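# Per-group diversity statistics: observed/expected heterozygosity,
# rarefied allelic richness, inbreeding coefficient.

# individuals belonging to `unit` at grouping `level`
unit_rows <- function(g, map, unit, level) {
  labels <- map_level(map, g$sample_ids, level)
  rows <- which(labels == unit)
  if (!length(rows)) {
    stop_pstfst(sprintf("no individuals in %s '%s'", level, unit),
                "pstfst_invalid_input")
  }
  rows
}

# per-locus genotyped count, alt-allele frequency and heterozygote
# proportion for a set of rows
locus_stats <- function(d) {
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Observed heterozygosity within a group
#'
#' Per locus, the fraction of non-missing genotypes that are heterozygous;
#' the group summary averages over loci polymorphic within the group by
#' default (the convention under which such tables are usually reported),
#' or over all genotyped loci with `polymorphic_only = FALSE`.
#'
#' @param g A [geno_matrix()].
#' @param map A [pop_map()].
#' @param unit Group label.
#' @param level Grouping level, `"region"` (default), `"population"` or
#'   `"range"`.
#' @param polymorphic_only Average only over loci polymorphic in the group.
#' @return List with `per_locus` (named numeric) and `mean`.
#' @export
observed_heterozygosity <- function(g, map, unit, level = "region",
                                    polymorphic_only = TRUE) {
  rows <- unit_rows(g, map, unit, level)
  st <- locus_stats(g$dosage[rows, , drop = FALSE])
  if (all(st$n == 0)) {
    stop_pstfst("no genotyped data in group", "pstfst_invalid_input")
  }
  ho <- st$h
  keep <- st$n > 0
  if (polymorphic_only) keep <- keep & st$p > 0 & st$p < 1
  list(per_locus = stats::setNames(ho, g$locus_meta$id),
       mean = mean(ho[keep]))
}

#' Expected heterozygosity within a group
#'
#' Per locus `He = 2 p (1 - p)` from the non-missing allele frequency
#' (optionally with the `2n/(2n - 1)` small-sample correction); group
#' summary as in [observed_heterozygosity()].
#'
#' @inheritParams observed_heterozygosity
#' @param unbiased Apply the `2n/(2n-1)` unbiased-variance correction.
#' @return List with `per_locus` and `mean`.
#' @export
expected_heterozygosity <- function(g, map, unit, level = "region",
                                    polymorphic_only = TRUE,
                                    unbiased = FALSE) {
  rows <- unit_rows(g, map, unit, level)
  st <- locus_stats(g$dosage[rows, , drop = FALSE])
  if (all(st$n == 0)) {
    stop_pstfst("no genotyped data in group", "pstfst_invalid_input")
  }
  he <- 2 * st$p * (1 - st$p)
  if (unbiased) he <- he * ifelse(st$n > 0, 2 * st$n / (2 * st$n - 1), NA)
  keep <- st$n > 0
  if (polymorphic_only) keep <- keep & st$p > 0 & st$p < 1
  list(per_locus = stats::setNames(he, g$locus_meta$id),
       mean = mean(he[keep]))
}

#' Rarefied allelic richness within a group
#'
#' Expected number of distinct alleles in a random subsample of
#' `g_rarefaction` allele copies, computed per locus by the hypergeometric
#' rarefaction formula `Ar = sum_a (1 - choose(2N - n_a, g) / choose(2N, g))`
#' and averaged over loci. For biallelic loci `Ar` lies in `[1, 2]`. When
#' `g_rarefaction` is `NULL` it defaults to twice the smallest per-locus
#' genotyped count across all groups at `level`, the largest size every
#' group can support.
#'
#' @inheritParams observed_heterozygosity
#' @param g_rarefaction Number of allele copies to rarefy to (>= 2).
#' @return List with `per_locus`, `mean` and the `g_rarefaction` used.
#' @export
allelic_richness <- function(g, map, unit, level = "region",
                             g_rarefaction = NULL) {
  if (is.null(g_rarefaction)) {
    g_rarefaction <- rarefaction_size(g, map, level)
  }
  check_count(g_rarefaction, "g_rarefaction", min = 2L)
  rows <- unit_rows(g, map, unit, level)
  d <- g$dosage[rows, , drop = FALSE]
  n <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  two_n <- 2 * n
  rare <- function(n_allele) {
    # P(allele absent from subsample) via log-binomials; lchoose(k, g) is
    # -Inf for k < g, giving probability 0 as required
    1 - exp(lchoose(two_n - n_allele, g_rarefaction) -
              lchoose(two_n, g_rarefaction))
  }
  ar <- rare(alt) + rare(two_n - alt)
  ar[two_n < g_rarefaction] <- NA_real_
  ar[n == 0] <- NA_real_
  list(per_locus = stats::setNames(ar, g$locus_meta$id),
       mean = mean(ar, na.rm = TRUE),
       g_rarefaction = g_rarefaction)
}

#' Largest rarefaction size supported by every group
#'
#' @inheritParams observed_heterozygosity
#' @return Twice the smallest per-locus genotyped count over groups and loci.
#' @export
rarefaction_size <- function(g, map, level = "region") {
  labels <- map_level(map, g$sample_ids, level)
  mins <- vapply(unique(labels), function(u) {
    min(colSums(!is.na(g$dosage[labels == u, , drop = FALSE])))
  }, numeric(1))
  size <- 2L * as.integer(min(mins))
  if (size < 2L) {
    stop_pstfst("a group has a locus with no genotyped individuals; set g_rarefaction explicitly",
                "pstfst_invalid_input")
  }
  size
}

#' Inbreeding coefficient within a group
#'
#' `F_IS = 1 - sum(Ho_l) / sum(He_l)` over loci polymorphic within the
#' group (a ratio of sums, not a mean of ratios). Returns `NA` with a
#' warning when the group is monomorphic at every locus.
#'
#' @inheritParams observed_heterozygosity
#' @return Scalar `F_IS` (or `NA`).
#' @export
inbreeding_coefficient <- function(g, map, unit, level = "region") {
  rows <- unit_rows(g, map, unit, level)
  st <- locus_stats(g$dosage[rows, , drop = FALSE])
  poly <- st$n > 0 & st$p > 0 & st$p < 1
  if (!any(poly)) {
    warning(sprintf("group '%s' is monomorphic at every locus; F_IS undefined",
                    unit))
    return(NA_real_)
  }
  ho <- st$h[poly]
  he <- 2 * st$p[poly] * (1 - st$p[poly])
  1 - sum(ho) / sum(he)
}

#' Per-group diversity summary table
#'
#' One row per group at `level`: sample size, rarefied allelic richness,
#' observed and expected heterozygosity, inbreeding coefficient, and
#' (optionally) the linkage-disequilibrium effective population size.
#'
#' @inheritParams observed_heterozygosity
#' @param g_rarefaction Rarefaction size; `NULL` for the automatic maximum.
#' @param ne Also compute [ld_ne()] per group (slower).
#' @param ne_maf_crit Allele-frequency floor passed to [ld_ne()].
#' @return Data frame with columns `unit, N, Ar, Ho, He, Fis` and, when
#'   `ne = TRUE`, `Ne, Ne_lo, Ne_hi`.
#' @export
diversity_table <- function(g, map, level = "region", g_rarefaction = NULL,
                            ne = FALSE, ne_maf_crit = 0.05) {
  labels <- map_level(map, g$sample_ids, level)
  units <- unique(labels)
  if (is.null(g_rarefaction)) g_rarefaction <- rarefaction_size(g, map, level)
  rows <- lapply(units, function(u) {
    n_ind <- sum(labels == u)
    ar <- allelic_richness(g, map, u, level, g_rarefaction)$mean
    ho <- observed_heterozygosity(g, map, u, level)$mean
    he <- expected_heterozygosity(g, map, u, level)$mean
    fis <- inbreeding_coefficient(g, map, u, level)
    out <- data.frame(unit = u, N = n_ind, Ar = ar, Ho = ho, He = he,
                      Fis = fis, stringsAsFactors = FALSE)
    if (ne) {
      est <- tryCatch(ld_ne(g, map, u, level = level, maf_crit = ne_maf_crit),
                      pstfst_error = function(e) NULL)
      out$Ne <- if (is.null(est)) NA_real_ else est$ne
      out$Ne_lo <- if (is.null(est) || is.null(est$ci)) NA_real_ else est$ci[1]
      out$Ne_hi <- if (is.null(est) || is.null(est$ci)) NA_real_ else est$ci[2]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
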