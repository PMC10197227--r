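# Site filtering reproducing the conventional VCFtools triplet: biallelic
# SNPs only, per-population genotyping proportion, global minor allele
# frequency.

#' Site-filter configuration
#'
#' @param biallelic_only Drop sites with more than one ALT allele.
#' @param drop_indels Drop sites whose REF or ALT is longer than one base.
#' @param min_pop_call_rate Minimum genotyping proportion that every
#'   population must reach at a site (default 0.9).
#' @param min_maf Minor-allele-frequency floor, applied strictly
#'   (`MAF > min_maf`) over the whole dataset (default 0.05).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(biallelic_only = TRUE, drop_indels = TRUE,
                          min_pop_call_rate = 0.9, min_maf = 0.05) {
  cfg <- list(
    biallelic_only = isTRUE(biallelic_only),
    drop_indels = isTRUE(drop_indels),
    min_pop_call_rate = check_number(min_pop_call_rate, "min_pop_call_rate",
                                     0, 1),
    min_maf = check_number(min_maf, "min_maf", 0, 1)
  )
  class(cfg) <- "filter_config"
  cfg
}

#' Apply site filters to a genotype matrix
#'
#' Rules are applied in a fixed order: (1) indel/multiallelic removal, (2)
#' per-population call rate — every population in the map must reach
#' `min_pop_call_rate` at the site, (3) global minor allele frequency,
#' computed on non-missing alleles across all mapped individuals and applied
#' strictly (a site at exactly `min_maf` is removed). Samples absent from
#' the map are dropped with a warning before filtering, mirroring the
#' behaviour of VCF tooling run with a keep-list. The operation is
#' idempotent.
#'
#' @param g A [geno_matrix()].
#' @param map A [pop_map()].
#' @param cfg A [filter_config()].
#' @return A list with `genotypes` (the filtered [geno_matrix()]) and `log`,
#'   a list with per-rule removal counts (`n_input`, `removed_not_biallelic`,
#'   `removed_call_rate`, `removed_maf`, `n_output`, `dropped_samples`).
#' @export
apply_filters <- function(g, map, cfg = filter_config()) {
  unmapped <- setdiff(g$sample_ids, map$individual)
  if (length(unmapped)) {
    warning(sprintf("dropping %d sample(s) absent from the population map",
                    length(unmapped)))
    g <- subset_geno(g, individuals = setdiff(g$sample_ids, unmapped))
  }
  d <- g$dosage
  meta <- g$locus_meta
  n_input <- ncol(d)

  # rule 1: biallelic SNPs only
  bad1 <- rep(FALSE, n_input)
  if (cfg$biallelic_only) bad1 <- bad1 | meta$multiallelic
  if (cfg$drop_indels) {
    bad1 <- bad1 | nchar(meta$ref) > 1 |
      vapply(strsplit(meta$alt, ","), function(a) any(nchar(a) > 1),
             logical(1))
  }
  keep <- !bad1
  removed_biallelic <- sum(bad1)

  # rule 2: per-population call rate on the surviving sites
  pops <- map_level(map, g$sample_ids, "population")
  ok <- rep(TRUE, n_input)
  for (p in unique(pops)) {
    rows <- which(pops == p)
    cr <- colMeans(!is.na(d[rows, , drop = FALSE]))
    ok <- ok & cr >= cfg$min_pop_call_rate
  }
  bad2 <- keep & !ok
  removed_call <- sum(bad2)
  keep <- keep & ok

  # rule 3: global MAF, strict inequality
  alt_count <- colSums(d, na.rm = TRUE)
  called <- colSums(!is.na(d))
  p_alt <- ifelse(called > 0, alt_count / (2 * called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  bad3 <- keep & !(is.finite(maf) & maf > cfg$min_maf)
  removed_maf <- sum(bad3)
  keep <- keep & !bad3

  if (!any(keep)) {
    stop_pstfst("no sites survive filtering", "pstfst_empty_result")
  }
  out <- subset_geno(g, loci = which(keep))
  log <- list(
    n_input = n_input,
    removed_not_biallelic = removed_biallelic,
    removed_call_rate = removed_call,
    removed_maf = removed_maf,
    n_output = ncol(out$dosage),
    dropped_samples = unmapped
  )
  list(genotypes = out, log = log)
}

#' Align genotype, map and trait datasets on shared individuals
#'
#' Genotype-only individuals are legitimate for population-genetic
#' statistics and trait-only individuals for Pst inference (glasshouse
#' phenotyping and sequencing typically cover overlapping but unequal
#' sets), so neither side is forced into the other; each dataset is only
#' restricted to individuals present in the map.
#'
#' @param g A [geno_matrix()] or `NULL`.
#' @param map A [pop_map()].
#' @param traits A [trait_table()] or `NULL`.
#' @param require_overlap If `TRUE`, error when the genotyped and phenotyped
#'   sets are disjoint (needed by joint analyses).
#' @return A list `(genotypes, map, traits, shared_ids)`.
#' @export
align_datasets <- function(g = NULL, map, traits = NULL,
                           require_overlap = FALSE) {
  g_ids <- if (!is.null(g)) intersect(g$sample_ids, map$individual) else character(0)
  t_ids <- if (!is.null(traits)) intersect(unique(traits$individual),
                                           map$individual) else character(0)
  if (!is.null(g) && length(g_ids) < length(g$sample_ids)) {
    g <- subset_geno(g, individuals = g_ids)
  }
  if (!is.null(traits)) {
    traits <- trait_table(traits[traits$individual %in% t_ids, , drop = FALSE],
                          map)
  }
  shared <- intersect(g_ids, t_ids)
  if (require_overlap && !is.null(g) && !is.null(traits) &&
      length(shared) == 0L) {
    stop_pstfst("genotyped and phenotyped individuals are disjoint",
                "pstfst_alignment_error")
  }
  list(genotypes = g, map = map, traits = traits, shared_ids = shared)
}
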