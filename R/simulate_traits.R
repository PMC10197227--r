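# Synthetic common-garden traits with known variance components.

#' Configuration for the trait simulator
#'
#' @param sigma2_between Variance among top-level units (regions or ranges).
#' @param sigma2_pop Variance among populations within a unit.
#' @param sigma2_resid Residual variance among individuals.
#' @param grand_mean Overall trait mean.
#' @param h2 Assumed heritability, in (0, 1]; enters the true-Pst formula
#'   recorded in the truth file, defaulting to 1 as is conventional for
#'   phenotypic (common-garden) divergence indices.
#' @param trait_name Label used in the output table.
#' @param seed Integer seed.
#' @return A list of class `trait_sim_config`.
#' @export
trait_sim_config <- function(sigma2_between = 1, sigma2_pop = 0.5,
                             sigma2_resid = 1, grand_mean = 0, h2 = 1,
                             trait_name = "trait1", seed = 1L) {
  cfg <- list(
    sigma2_between = check_number(sigma2_between, "sigma2_between", 0),
    sigma2_pop = check_number(sigma2_pop, "sigma2_pop", 0),
    sigma2_resid = check_number(sigma2_resid, "sigma2_resid", 0),
    grand_mean = check_number(grand_mean, "grand_mean"),
    h2 = check_number(h2, "h2", 0, 1, strict_lower = TRUE),
    trait_name = as.character(trait_name),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$sigma2_between + cfg$sigma2_pop + cfg$sigma2_resid <= 0) {
    stop_pstfst("at least one variance component must be positive",
                "pstfst_invalid_parameter")
  }
  class(cfg) <- "trait_sim_config"
  cfg
}

#' The Pst variance-ratio formula
#'
#' `Pst = sigma2_B / (sigma2_B + 2 * h2 * sigma2_W)`, the phenotypic
#' analogue of Qst. Under the package's default convention the within-unit
#' variance `sigma2_W` pools the population and residual components.
#'
#' @param sigma2_between Among-unit variance.
#' @param sigma2_within Within-unit variance.
#' @param h2 Heritability in (0, 1].
#' @return Pst in `[0, 1]`.
#' @export
pst_formula <- function(sigma2_between, sigma2_within, h2 = 1) {
  denom <- sigma2_between + 2 * h2 * sigma2_within
  ifelse(denom == 0, 0, sigma2_between / denom)
}

#' Simulate individual trait values over a population map
#'
#' Gaussian random-effects draw `y_i = mu + a_unit(i) + b_pop(i) + e_i` with
#' `a ~ N(0, sigma2_between)`, `b ~ N(0, sigma2_pop)` and
#' `e ~ N(0, sigma2_resid)`, matching the hierarchical model fitted at
#' inference time.
#'
#' @param map A [pop_map()].
#' @param config A [trait_sim_config()].
#' @param unit Grouping level acting as the top of the hierarchy:
#'   `"region"` (default) or `"range"`.
#' @return A list with `traits` (a [trait_table()]) and `truth` (configured
#'   variances, drawn unit and population effects, and the true Pst implied
#'   by the configured variances under the `sigma2_W = sigma2_pop +
#'   sigma2_resid` convention).
#' @export
simulate_traits <- function(map, config, unit = c("region", "range")) {
  stopifnot(inherits(config, "trait_sim_config"))
  unit <- match.arg(unit)
  if (nrow(map) == 0L) {
    stop_pstfst("population map is empty", "pstfst_invalid_input")
  }
  set.seed(config$seed)
  units <- unique(map[[unit]])
  pops <- unique(map$population)
  a <- stats::rnorm(length(units), 0, sqrt(config$sigma2_between))
  b <- stats::rnorm(length(pops), 0, sqrt(config$sigma2_pop))
  names(a) <- units; names(b) <- pops
  e <- stats::rnorm(nrow(map), 0, sqrt(config$sigma2_resid))
  y <- config$grand_mean + a[map[[unit]]] + b[map$population] + e
  traits <- trait_table(data.frame(
    individual = map$individual,
    trait = config$trait_name,
    value = as.numeric(y),
    stringsAsFactors = FALSE
  ), map)
  truth <- list(
    config = unclass(config),
    unit_level = unit,
    unit_effects = a,
    pop_effects = b,
    true_pst = pst_formula(config$sigma2_between,
                           config$sigma2_pop + config$sigma2_resid,
                           config$h2)
  )
  list(traits = traits, truth = truth)
}
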