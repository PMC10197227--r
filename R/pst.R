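# Bayesian Pst inference: Gibbs sampling of the hierarchical trait model
# y = mu + a_unit + b_pop + e, posterior Pst, the Pst - Fst difference and
# its credibility-interval classification.

#' Configuration for the Pst model
#'
#' @param h2 Assumed heritability in (0, 1] (default 1, the standard
#'   assumption for phenotypic divergence indices).
#' @param n_chains Number of independent chains (default 5).
#' @param n_iter Post-burn-in iterations per chain (default 50000).
#' @param n_burnin Burn-in iterations per chain (default 1000).
#' @param interval_mass Total mass of the equal-tailed credibility interval
#'   (default 0.975, i.e. quantiles 0.0125 and 0.9875; set 0.95 for a
#'   conventional 95% interval).
#' @param sigma_w_convention Which variance counts as "within-unit" in the
#'   Pst denominator: `"residual-plus-population"` (default; all phenotypic
#'   variance inside the compared units) or `"residual-only"`.
#' @param prior Prior family for the three variance components.
#'   `"half-cauchy"` (default) places a half-Cauchy prior on each standard
#'   deviation, implemented through its conjugate inverse-gamma mixture so
#'   the sampler stays a pure Gibbs scheme; it remains well behaved when a
#'   variance is informed by very few effects, which is always the case
#'   here because every comparison has exactly two top-level units.
#'   `"inverse-gamma"` is the historical vague choice
#'   `IG(prior_var_shape, prior_var_rate)` on each variance; its heavy
#'   upper tail inflates Pst in two-unit comparisons and it is kept for
#'   comparability only.
#' @param prior_scale Scale of the half-Cauchy prior; `NA` (default) uses
#'   `sqrt(var(y) / 3)` — the standard deviation each component would have
#'   if the three components split the observed trait variance equally —
#'   which also keeps Pst invariant under affine rescaling of the trait.
#' @param prior_mu_var Prior variance of the grand mean (default 1e6).
#' @param prior_var_shape,prior_var_rate Inverse-gamma parameters used when
#'   `prior = "inverse-gamma"` (default 0.001 and 0.001).
#' @param seed Integer seed; chains receive derived sub-seeds.
#' @return A list of class `pst_config`.
#' @export
pst_config <- function(h2 = 1, n_chains = 5L, n_iter = 50000L,
                       n_burnin = 1000L, interval_mass = 0.975,
                       sigma_w_convention = c("residual-plus-population",
                                              "residual-only"),
                       prior = c("half-cauchy", "inverse-gamma"),
                       prior_scale = NA, prior_mu_var = 1e6,
                       prior_var_shape = 0.001, prior_var_rate = 0.001,
                       seed = 1L) {
  cfg <- list(
    h2 = check_number(h2, "h2", 0, 1, strict_lower = TRUE),
    n_chains = check_count(n_chains, "n_chains"),
    n_iter = check_count(n_iter, "n_iter", min = 1000L),
    n_burnin = check_count(n_burnin, "n_burnin", min = 0L),
    interval_mass = check_number(interval_mass, "interval_mass", 0, 1,
                                 strict_lower = TRUE, strict_upper = TRUE),
    sigma_w_convention = match.arg(sigma_w_convention),
    prior = match.arg(prior),
    prior_scale = if (is.na(prior_scale)) NA_real_ else
      check_number(prior_scale, "prior_scale", 0, strict_lower = TRUE),
    prior_mu_var = check_number(prior_mu_var, "prior_mu_var", 0,
                                strict_lower = TRUE),
    prior_var_shape = check_number(prior_var_shape, "prior_var_shape", 0,
                                   strict_lower = TRUE),
    prior_var_rate = check_number(prior_var_rate, "prior_var_rate", 0,
                                  strict_lower = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  class(cfg) <- "pst_config"
  cfg
}

# one Gibbs chain; returns an iterations x 4 matrix (mu, s2B, s2P, s2e).
# Half-Cauchy priors on standard deviations use the conjugate scale-mixture
# representation sigma2 | lambda ~ IG(1/2, 1/lambda),
# lambda ~ IG(1/2, 1/scale^2), which marginally gives
# sigma ~ half-Cauchy(scale) while keeping every update conjugate.
gibbs_chain <- function(y, u, p, n_u, n_p, cfg, chain_seed, init_scale) {
  set.seed(chain_seed)
  n <- length(y)
  U <- length(n_u); P <- length(n_p)
  half_cauchy <- cfg$prior == "half-cauchy"
  a0 <- cfg$prior_var_shape; b0 <- cfg$prior_var_rate
  hc_scale <- cfg$prior_scale
  if (half_cauchy && is.na(hc_scale)) {
    hc_scale <- max(stats::sd(y) / sqrt(3), 1e-8)
  }
  # method-of-moments starting values, overdispersed per chain
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  s2B <- max(vy / 3, 1e-8) * init_scale[1]
  s2P <- max(vy / 3, 1e-8) * init_scale[2]
  s2e <- max(vy / 3, 1e-8) * init_scale[3]
  lamB <- lamP <- lame <- 1
  mu <- mean(y)
  a <- rep(0, U); b <- rep(0, P)
  total <- cfg$n_burnin + cfg$n_iter
  out <- matrix(NA_real_, cfg$n_iter, 4,
                dimnames = list(NULL, c("mu", "sigma2_B", "sigma2_P",
                                        "sigma2_e")))
  for (it in seq_len(total)) {
    # grand mean
    r <- y - a[u] - b[p]
    prec <- n / s2e + 1 / cfg$prior_mu_var
    mu <- stats::rnorm(1, (sum(r) / s2e) / prec, sqrt(1 / prec))
    # unit effects
    r <- y - mu - b[p]
    su <- rowsum(r, u, reorder = TRUE)[, 1]
    Va <- 1 / (n_u / s2e + 1 / s2B)
    a <- stats::rnorm(U, Va * su / s2e, sqrt(Va))
    # population effects
    r <- y - mu - a[u]
    sp <- rowsum(r, p, reorder = TRUE)[, 1]
    Vb <- 1 / (n_p / s2e + 1 / s2P)
    b <- stats::rnorm(P, Vb * sp / s2e, sqrt(Vb))
    # variances
    e <- y - mu - a[u] - b[p]
    if (half_cauchy) {
      s2B <- 1 / stats::rgamma(1, 0.5 + U / 2, 1 / lamB + sum(a^2) / 2)
      lamB <- 1 / stats::rgamma(1, 1, 1 / hc_scale^2 + 1 / s2B)
      s2P <- 1 / stats::rgamma(1, 0.5 + P / 2, 1 / lamP + sum(b^2) / 2)
      lamP <- 1 / stats::rgamma(1, 1, 1 / hc_scale^2 + 1 / s2P)
      s2e <- 1 / stats::rgamma(1, 0.5 + n / 2, 1 / lame + sum(e^2) / 2)
      lame <- 1 / stats::rgamma(1, 1, 1 / hc_scale^2 + 1 / s2e)
    } else {
      s2B <- 1 / stats::rgamma(1, a0 + U / 2, b0 + sum(a^2) / 2)
      s2P <- 1 / stats::rgamma(1, a0 + P / 2, b0 + sum(b^2) / 2)
      s2e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
    }
    if (it > cfg$n_burnin) {
      out[it - cfg$n_burnin, ] <- c(mu, s2B, s2P, s2e)
    }
  }
  out
}

# classic Gelman-Rubin potential scale reduction factor
gelman_rubin <- function(chain_list) {
  m <- length(chain_list)
  if (m < 2) return(NA_real_)
  n <- nrow(chain_list[[1]])
  means <- vapply(chain_list, colMeans, numeric(ncol(chain_list[[1]])))
  vars <- vapply(chain_list, function(ch) apply(ch, 2, stats::var),
                 numeric(ncol(chain_list[[1]])))
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}

#' Fit the hierarchical trait model by Gibbs sampling
#'
#' Model: `y_i = mu + a_{unit(i)} + b_{pop(i)} + e_i` with
#' `a ~ N(0, sigma2_B)`, `b ~ N(0, sigma2_P)`, `e ~ N(0, sigma2_e)`;
#' conjugate full-conditional updates (normal for the mean and effects,
#' inverse-gamma for the variances), several chains with overdispersed
#' initialization (variances scaled log-uniformly over `[1e-2, 1e2]` times
#' the method-of-moments values), all post-burn-in draws retained without
#' thinning, and Gelman-Rubin R-hat per variance component.
#'
#' @param traits A [trait_table()] holding exactly one trait (subset first
#'   or pass `trait`).
#' @param map A [pop_map()].
#' @param cfg A [pst_config()].
#' @param trait Trait name to select when `traits` holds several.
#' @param unit_level Top level of the hierarchy: `"region"` (default) or
#'   `"range"`.
#' @param units Optional subset of unit labels defining the comparison
#'   (e.g. a pair of regions); default all units present.
#' @return An object of class `pst_posterior`: list with `draws` (pooled
#'   matrix over chains: columns `mu`, `sigma2_B`, `sigma2_P`, `sigma2_e`),
#'   `chains` (list of per-chain matrices), `rhat`, `n_obs`, `unit_level`,
#'   `units`, and the `cfg` used.
#' @export
gibbs_fit <- function(traits, map, cfg = pst_config(), trait = NULL,
                      unit_level = c("region", "range"), units = NULL) {
  unit_level <- match.arg(unit_level)
  stopifnot(inherits(cfg, "pst_config"))
  df <- as.data.frame(traits)
  if (!is.null(trait)) df <- df[df$trait == trait, , drop = FALSE]
  if (length(unique(df$trait)) != 1L) {
    stop_pstfst("exactly one trait must be selected (use `trait`)",
                "pstfst_invalid_input")
  }
  ulab <- map_level(map, df$individual, unit_level)
  plab <- map_level(map, df$individual, "population")
  if (!is.null(units)) {
    keep <- ulab %in% units
    df <- df[keep, , drop = FALSE]
    ulab <- ulab[keep]; plab <- plab[keep]
  }
  y <- df$value
  if (any(!is.finite(y))) {
    stop_pstfst("non-finite trait values", "pstfst_invalid_input")
  }
  uf <- factor(ulab); pf <- factor(plab)
  if (nlevels(uf) < 2) {
    stop_pstfst("fewer than 2 units in the comparison", "pstfst_invalid_input")
  }
  if (nlevels(pf) < 2) {
    stop_pstfst("fewer than 2 populations", "pstfst_invalid_input")
  }
  pop_n <- table(pf)
  if (any(pop_n < 3)) {
    warning(sprintf("%d population(s) have fewer than 3 individuals",
                    sum(pop_n < 3)))
  }
  if (stats::var(y) == 0) {
    warning("all trait values identical; variance components collapse toward the prior floor")
  }
  u <- as.integer(uf); p <- as.integer(pf)
  n_u <- as.numeric(table(u)); n_p <- as.numeric(table(p))
  seeds <- derive_seeds(cfg$seed, cfg$n_chains, stream = 7L)
  chains <- vector("list", cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(seeds[ch])
    init_scale <- 10^stats::runif(3, -2, 2)
    chains[[ch]] <- gibbs_chain(y, u, p, n_u, n_p, cfg, seeds[ch] + 1L,
                                init_scale)
  }
  rhat <- gelman_rubin(chains)
  names(rhat) <- colnames(chains[[1]])
  structure(list(
    draws = do.call(rbind, chains),
    chains = chains,
    rhat = rhat,
    n_obs = length(y),
    unit_level = unit_level,
    units = levels(uf),
    trait = unique(df$trait),
    cfg = cfg
  ), class = "pst_posterior")
}

#' @export
print.pst_posterior <- function(x, ...) {
  cat(sprintf("<pst_posterior> trait '%s', %s-level (%s), %d draws\n",
              x$trait, x$unit_level, paste(x$units, collapse = ", "),
              nrow(x$draws)))
  if ("pst" %in% colnames(x$draws)) {
    s <- pst_summary(x)
    cat(sprintf("  Pst = %.3f (%.3f-%.3f)\n", s$mean, s$lo, s$hi))
  }
  invisible(x)
}

#' Transform variance-component draws to Pst draws
#'
#' Applies `Pst = sigma2_B / (sigma2_B + 2 h2 sigma2_W)` to every draw,
#' with `sigma2_W` set by the configured convention (population-plus-
#' residual variance by default, residual only as an option).
#'
#' @param posterior A [gibbs_fit()] result.
#' @return The posterior with a `pst` column added to `draws` and each
#'   chain.
#' @export
pst_transform <- function(posterior) {
  stopifnot(inherits(posterior, "pst_posterior"))
  cfg <- posterior$cfg
  w <- function(dr) {
    if (cfg$sigma_w_convention == "residual-plus-population") {
      dr[, "sigma2_P"] + dr[, "sigma2_e"]
    } else {
      dr[, "sigma2_e"]
    }
  }
  add <- function(dr) {
    cbind(dr, pst = pst_formula(dr[, "sigma2_B"], w(dr), cfg$h2))
  }
  posterior$draws <- add(posterior$draws)
  posterior$chains <- lapply(posterior$chains, add)
  posterior
}

#' Posterior summary of Pst
#'
#' @param posterior A [pst_transform()]ed posterior.
#' @return List with `mean`, `lo`, `hi` (equal-tailed interval at the
#'   configured mass).
#' @export
pst_summary <- function(posterior) {
  if (!"pst" %in% colnames(posterior$draws)) {
    posterior <- pst_transform(posterior)
  }
  qs <- stats::quantile(posterior$draws[, "pst"],
                        interval_probs(posterior$cfg$interval_mass),
                        names = FALSE)
  list(mean = mean(posterior$draws[, "pst"]), lo = qs[1], hi = qs[2])
}

#' Classify a Pst - Fst interval
#'
#' The decision rule on the credibility interval of the difference:
#' entirely above zero is evidence of divergent selection on the trait,
#' entirely below zero of stabilizing selection, and an interval
#' overlapping zero is consistent with genetic drift.
#'
#' @param lo,hi Lower and upper interval bounds.
#' @return `"divergent"`, `"stabilizing"`, or `"drift-consistent"`.
#' @export
classify_divergence <- function(lo, hi) {
  stopifnot(length(lo) == length(hi), all(lo <= hi))
  ifelse(lo > 0, "divergent",
         ifelse(hi < 0, "stabilizing", "drift-consistent"))
}

#' Compare posterior Pst with a neutral Fst value
#'
#' Subtracts a scalar mean Fst from every Pst draw (or pairs each draw with
#' a uniformly resampled value when a vector of bootstrap Fst draws is
#' supplied), summarizes the difference with an equal-tailed interval at
#' the configured mass, and classifies the trait by [classify_divergence()].
#'
#' @param posterior A [gibbs_fit()] result (transformed automatically).
#' @param fst Scalar mean Fst in `[0, 1]`, or a numeric vector of Fst draws.
#' @param interval_mass Optional override of the configured interval mass.
#' @param seed Seed for the Fst-draw resampling (only used for vector
#'   `fst`).
#' @return List with `pst` (mean, lo, hi), `diff` (mean, lo, hi),
#'   `classification`, `fst_mean`, and `rhat`.
#' @export
pst_fst_compare <- function(posterior, fst, interval_mass = NULL, seed = 1L) {
  if (any(!is.finite(fst)) || any(fst < 0) || any(fst > 1)) {
    stop_pstfst("fst values must lie in [0, 1]", "pstfst_invalid_parameter")
  }
  if (!"pst" %in% colnames(posterior$draws)) {
    posterior <- pst_transform(posterior)
  }
  mass <- if (is.null(interval_mass)) posterior$cfg$interval_mass else
    check_number(interval_mass, "interval_mass", 0, 1, strict_lower = TRUE,
                 strict_upper = TRUE)
  pst_draws <- posterior$draws[, "pst"]
  if (length(fst) == 1L) {
    diff_draws <- pst_draws - fst
  } else {
    set.seed(seed)
    diff_draws <- pst_draws - sample(fst, length(pst_draws), replace = TRUE)
  }
  probs <- interval_probs(mass)
  dq <- stats::quantile(diff_draws, probs, names = FALSE)
  pq <- stats::quantile(pst_draws, probs, names = FALSE)
  list(
    pst = list(mean = mean(pst_draws), lo = pq[1], hi = pq[2]),
    diff = list(mean = mean(diff_draws), lo = dq[1], hi = dq[2]),
    classification = classify_divergence(dq[1], dq[2]),
    fst_mean = mean(fst),
    rhat = posterior$rhat
  )
}

#' Pst - Fst comparison for every trait and comparison
#'
#' Runs [gibbs_fit()], [pst_transform()] and [pst_fst_compare()] for each
#' trait in the table crossed with each requested comparison: the
#' native/non-native range split and/or every pair of regions. Each
#' comparison must have a mean Fst in `fst_table` (as produced by
#' [fst_comparison_table()], typically on the neutral locus set).
#'
#' @param traits A [trait_table()].
#' @param map A [pop_map()].
#' @param fst_table Data frame with columns `level`, `unit_a`, `unit_b`,
#'   `fst`.
#' @param cfg A [pst_config()].
#' @param comparisons Which comparisons to run: `"range"`, `"pairwise"`, or
#'   both (default `"range"`).
#' @return Data frame with one row per trait x comparison: `trait`,
#'   `level`, `unit_a`, `unit_b`, `fst`, `pst_mean`, `pst_lo`, `pst_hi`,
#'   `diff_mean`, `diff_lo`, `diff_hi`, `classification`, `max_rhat`.
#' @export
run_all_comparisons <- function(traits, map, fst_table, cfg = pst_config(),
                                comparisons = "range") {
  comparisons <- match.arg(comparisons, c("range", "pairwise"),
                           several.ok = TRUE)
  jobs <- list()
  if ("range" %in% comparisons) {
    rt <- fst_table[fst_table$level == "range", , drop = FALSE]
    if (nrow(rt) != 1) {
      stop_pstfst("fst_table lacks the range-level comparison",
                  "pstfst_invalid_input")
    }
    jobs[[1]] <- list(level = "range", units = c(rt$unit_a, rt$unit_b),
                      fst = rt$fst)
  }
  if ("pairwise" %in% comparisons) {
    regions <- unique(map$region)
    for (i in seq_len(length(regions) - 1)) {
      for (j in seq((i + 1), length(regions))) {
        row <- fst_table[fst_table$level == "region" &
                           ((fst_table$unit_a == regions[i] &
                               fst_table$unit_b == regions[j]) |
                              (fst_table$unit_a == regions[j] &
                                 fst_table$unit_b == regions[i])), ,
                         drop = FALSE]
        if (nrow(row) != 1) {
          stop_pstfst(sprintf("fst_table lacks the comparison %s vs %s",
                              regions[i], regions[j]),
                      "pstfst_invalid_input")
        }
        jobs[[length(jobs) + 1L]] <- list(
          level = "region", units = c(regions[i], regions[j]),
          fst = row$fst)
      }
    }
  }
  trait_names <- unique(traits$trait)
  seeds <- derive_seeds(cfg$seed, length(jobs) * length(trait_names),
                        stream = 11L)
  out <- list(); k <- 0L
  for (tn in trait_names) {
    for (job in jobs) {
      k <- k + 1L
      cfg_k <- cfg; cfg_k$seed <- seeds[k]
      fit <- gibbs_fit(traits, map, cfg_k, trait = tn,
                       unit_level = if (job$level == "range") "range" else
                         "region",
                       units = job$units)
      cmp <- pst_fst_compare(fit, job$fst, seed = seeds[k])
      out[[k]] <- data.frame(
        trait = tn, level = job$level,
        unit_a = job$units[1], unit_b = job$units[2], fst = job$fst,
        pst_mean = cmp$pst$mean, pst_lo = cmp$pst$lo, pst_hi = cmp$pst$hi,
        diff_mean = cmp$diff$mean, diff_lo = cmp$diff$lo,
        diff_hi = cmp$diff$hi,
        classification = cmp$classification,
        max_rhat = max(cmp$rhat[c("sigma2_B", "sigma2_P", "sigma2_e")]),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
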