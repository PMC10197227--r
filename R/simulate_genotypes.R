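# Synthetic genotype generation under the Balding-Nichols model.
#
# The generator emulates a range-wide sampling design: a handful of
# geographic regions, several populations per region, and a balanced number
# of diploid individuals per population, genotyped at a few thousand
# anonymous biallelic SNPs with drift-level differentiation among regions
# (Fst on the order of 0.02-0.09) plus an optional minority of loci with
# elevated differentiation standing in for targets of divergent selection.

#' Configuration for the genotype simulator
#'
#' @param n_units Number of top-level groups (regions).
#' @param pops_per_unit Populations sampled within each region.
#' @param inds_per_pop Diploid individuals per population.
#' @param n_loci Number of biallelic SNP loci.
#' @param ancestral_maf_range Length-2 numeric in (0, 0.5]: the ancestral
#'   minor-allele frequency of each locus is drawn uniformly from this range
#'   (and assigned to the reference or alternate allele at random).
#' @param F_neutral Balding-Nichols drift parameter for region-level allele
#'   frequencies, in (0, 1); the expected multi-locus Weir-Cockerham theta
#'   among regions equals this value.
#' @param F_pop Second-level drift parameter for populations within a region;
#'   small by default, reflecting weak within-region substructure.
#' @param selected_fraction Proportion of loci simulated with elevated drift
#'   `F_selected` instead of `F_neutral`, in [0, 1).
#' @param F_selected Drift parameter of the selected loci; must be at least
#'   `F_neutral`.
#' @param missing_rate Probability that any single genotype call is missing,
#'   in [0, 0.5).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A list of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_units = 6L, pops_per_unit = 10L,
                            inds_per_pop = 3L, n_loci = 2000L,
                            ancestral_maf_range = c(0.1, 0.5),
                            F_neutral = 0.05, F_pop = 0.01,
                            selected_fraction = 0, F_selected = F_neutral,
                            missing_rate = 0.02, seed = 1L) {
  cfg <- list(
    n_units = check_count(n_units, "n_units"),
    pops_per_unit = check_count(pops_per_unit, "pops_per_unit"),
    inds_per_pop = check_count(inds_per_pop, "inds_per_pop"),
    n_loci = check_count(n_loci, "n_loci"),
    ancestral_maf_range = ancestral_maf_range,
    F_neutral = check_number(F_neutral, "F_neutral", 0, 1,
                             strict_lower = TRUE, strict_upper = TRUE),
    F_pop = check_number(F_pop, "F_pop", 0, 1, strict_upper = TRUE),
    selected_fraction = check_number(selected_fraction, "selected_fraction",
                                     0, 1, strict_upper = TRUE),
    F_selected = check_number(F_selected, "F_selected", 0, 1,
                              strict_lower = TRUE, strict_upper = TRUE),
    missing_rate = check_number(missing_rate, "missing_rate", 0, 0.5,
                                strict_upper = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(ancestral_maf_range) != 2L ||
      any(ancestral_maf_range <= 0) || any(ancestral_maf_range > 0.5) ||
      ancestral_maf_range[1] > ancestral_maf_range[2]) {
    stop_pstfst("`ancestral_maf_range` must be an increasing pair in (0, 0.5]",
                "pstfst_invalid_parameter")
  }
  if (cfg$F_selected < cfg$F_neutral) {
    stop_pstfst("`F_selected` must be >= `F_neutral`",
                "pstfst_invalid_parameter")
  }
  class(cfg) <- "geno_sim_config"
  cfg
}

#' Draw subpopulation allele frequencies under the Balding-Nichols model
#'
#' Each group's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is the ancestral frequency `p`
#' and whose variance is `F p (1-p)`; genotypes drawn binomially from these
#' frequencies have expected Weir-Cockerham theta equal to `F`.
#'
#' @param ancestral_freq Ancestral allele frequency, strictly in (0, 1).
#' @param F Drift parameter, strictly in (0, 1).
#' @param n_units Number of groups to draw.
#' @return Numeric vector of `n_units` frequencies in `[0, 1]`.
#' @export
simulate_subpopulation_frequencies <- function(ancestral_freq, F, n_units) {
  check_number(ancestral_freq, "ancestral_freq", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(F, "F", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_count(n_units, "n_units")
  shape <- (1 - F) / F
  stats::rbeta(n_units, ancestral_freq * shape, (1 - ancestral_freq) * shape)
}

#' Simulate a genotype matrix with known differentiation
#'
#' Two-level Balding-Nichols sampling: each region receives a frequency draw
#' at drift `F_neutral` (or `F_selected` for the selected loci), each
#' population within the region receives a second draw at drift `F_pop`
#' around the regional frequency, and diploid dosages are binomial draws
#' from the population frequency. Missing calls are assigned completely at
#' random at `missing_rate`.
#'
#' @param config A [geno_sim_config()].
#' @return A list with elements `genotypes` ([geno_matrix()]), `map`
#'   ([pop_map()]; the first half of the regions is labelled `"native"`, the
#'   rest `"non-native"`), and `truth` (a list recording the configuration,
#'   ancestral frequencies, per-region frequencies, and the indices and drift
#'   parameter of the selected loci).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "geno_sim_config"))
  set.seed(config$seed)
  U <- config$n_units; P <- config$pops_per_unit; I <- config$inds_per_pop
  L <- config$n_loci
  n_pops <- U * P
  n_ind <- n_pops * I

  maf <- stats::runif(L, config$ancestral_maf_range[1],
                      config$ancestral_maf_range[2])
  flip <- stats::runif(L) < 0.5
  p_anc <- ifelse(flip, 1 - maf, maf)

  n_sel <- floor(config$selected_fraction * L)
  selected <- if (n_sel > 0) sort(sample.int(L, n_sel)) else integer(0)
  F_locus <- rep(config$F_neutral, L)
  F_locus[selected] <- config$F_selected

  # region-level frequencies: loci x units
  shape <- (1 - F_locus) / F_locus
  p_unit <- matrix(stats::rbeta(L * U, rep(p_anc * shape, U),
                                rep((1 - p_anc) * shape, U)),
                   nrow = L, ncol = U)
  # population-level frequencies: loci x (units*pops); F_pop = 0 collapses
  # to the regional draw
  if (config$F_pop > 0) {
    sp <- (1 - config$F_pop) / config$F_pop
    pu <- p_unit[, rep(seq_len(U), each = P), drop = FALSE]
    # Beta is degenerate at fixed frequencies; keep 0/1 exactly
    p_pop <- matrix(0, nrow = L, ncol = n_pops)
    interior <- pu > 0 & pu < 1
    p_pop[interior] <- stats::rbeta(sum(interior), pu[interior] * sp,
                                    (1 - pu[interior]) * sp)
    p_pop[!interior] <- pu[!interior]
  } else {
    p_pop <- p_unit[, rep(seq_len(U), each = P), drop = FALSE]
  }

  pop_of_ind <- rep(seq_len(n_pops), each = I)
  # dosages: individuals x loci
  dosage <- matrix(stats::rbinom(n_ind * L, 2L,
                                 t(p_pop)[pop_of_ind, , drop = FALSE]),
                   nrow = n_ind, ncol = L)
  if (config$missing_rate > 0) {
    dosage[stats::runif(n_ind * L) < config$missing_rate] <- NA_integer_
  }

  unit_names <- sprintf("region%02d", seq_len(U))
  pop_names <- sprintf("%s_pop%02d", rep(unit_names, each = P),
                       rep(seq_len(P), U))
  ind_ids <- sprintf("%s_ind%03d", pop_names[pop_of_ind],
                     unlist(lapply(seq_len(n_pops), function(i) seq_len(I))))
  range_of_unit <- ifelse(seq_len(U) <= ceiling(U / 2), "native", "non-native")

  map <- pop_map(data.frame(
    individual = ind_ids,
    population = pop_names[pop_of_ind],
    region = rep(unit_names, each = P * I),
    range = rep(range_of_unit, each = P * I),
    stringsAsFactors = FALSE
  ))
  meta <- data.frame(
    chrom = "chr1",
    pos = seq_len(L) * 100L,
    id = sprintf("snp%05d", seq_len(L)),
    ref = "A", alt = "T",
    multiallelic = FALSE,
    stringsAsFactors = FALSE
  )
  g <- geno_matrix(dosage, meta, ind_ids)
  truth <- list(
    config = unclass(config),
    ancestral_freq = p_anc,
    unit_freq = p_unit,
    selected_loci = selected,
    selected_ids = meta$id[selected],
    F_selected = config$F_selected
  )
  list(genotypes = g, map = map, truth = truth)
}
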