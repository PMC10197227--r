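# Effective population size by the linkage-disequilibrium method:
# Burrows composite disequilibrium between locus pairs, squared correlation
# r^2, sample-size bias adjustment, and the random-mating drift formula.

# expected r^2 under no drift given sample size S (random mating)
ld_ne_bias <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2, 0.0018 + 0.907 / S + 4.44 / S^2)
}

# drift r^2 -> Ne, random mating; non-positive signal -> Inf
ld_ne_transform <- function(r2_drift) {
  if (!is.finite(r2_drift) || r2_drift <= 0) return(Inf)
  disc <- 1 / 9 - 2.76 * r2_drift
  if (disc < 0) return(Inf)
  (1 / 3 + sqrt(disc)) / (2 * r2_drift)
}

#' Effective population size by the linkage-disequilibrium method
#'
#' For every pair of polymorphic loci within the group, computes the
#' Burrows composite disequilibrium from genotype dosages over
#' pairwise-complete individuals, forms the squared allelic correlation
#' `r^2 = Delta^2 / (p(1-p) q(1-q))`, averages pairs weighted by their
#' sample size `S`, subtracts the expected no-drift value
#' (`1/S + 3.19/S^2` for `S >= 30`, `0.0018 + 0.907/S + 4.44/S^2` below),
#' and inverts the random-mating drift expectation
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`. A non-positive drift
#' signal yields `Ne = Inf`.
#'
#' @param g A [geno_matrix()].
#' @param map A [pop_map()].
#' @param unit Group label.
#' @param level Grouping level (default `"region"`).
#' @param maf_crit Minor-allele-frequency floor for loci entering the
#'   estimate (default 0.05, matching the conventional screening value).
#' @param jackknife Compute a delete-one-locus jackknife 95% interval.
#' @return List with `ne`, `r2_mean`, `r2_drift`, `n_loci`, `n_pairs`,
#'   `s_harmonic` and (if requested) `ci` (length-2, possibly infinite).
#' @export
ld_ne <- function(g, map, unit, level = "region", maf_crit = 0.05,
                  jackknife = TRUE) {
  rows <- unit_rows(g, map, unit, level)
  d <- g$dosage[rows, , drop = FALSE]
  if (nrow(d) < 10) {
    warning(sprintf("only %d individuals in '%s'; LD-Ne is unreliable below 10",
                    nrow(d), unit))
  }
  st <- locus_stats(d)
  keep <- st$n >= 2 & is.finite(st$p) &
    pmin(st$p, 1 - st$p) > maf_crit
  if (sum(keep) < 2) {
    stop_pstfst("fewer than 2 polymorphic loci pass maf_crit",
                "pstfst_invalid_input")
  }
  d <- d[, keep, drop = FALSE]
  L <- ncol(d)

  # pairwise-complete moments via masked cross-products
  M <- (!is.na(d)) * 1
  X <- d; X[is.na(X)] <- 0
  S <- crossprod(M)                  # pairwise sample sizes
  Sxy <- crossprod(X)                # sum x*y over complete pairs
  Sx <- crossprod(X, M)              # [j,k]: sum of x_j over pairs with k
  Sxx <- crossprod(X * X, M)         # [j,k]: sum of x_j^2 over those pairs
  mx <- Sx / S                       # mean dosage of row locus within pair
  # Burrows composite Delta = cov(X, Y)/2, with the S/(S-1) small-sample
  # factor conventionally applied by LD-Ne estimators
  delta <- (Sxy / S - mx * t(mx)) * (S / (S - 1)) / 2
  p <- mx / 2                        # row-locus allele freq within the pair
  denom <- (p * (1 - p)) * t(p * (1 - p))
  r2 <- delta^2 / denom

  up <- upper.tri(r2)
  ok <- up & is.finite(r2) & denom > 0 & S >= 2
  if (!any(ok)) {
    stop_pstfst("no usable locus pairs", "pstfst_invalid_input")
  }
  w <- S[ok]
  r2v <- r2[ok]
  r2_mean <- sum(w * r2v) / sum(w)
  bias <- sum(w * ld_ne_bias(S[ok])) / sum(w)
  r2_drift <- r2_mean - bias
  ne <- ld_ne_transform(r2_drift)

  ci <- NULL
  if (jackknife && L > 2) {
    # delete one locus at a time; recompute the weighted means from the
    # precomputed pair matrices
    okm <- matrix(FALSE, L, L); okm[ok] <- TRUE
    drifts <- vapply(seq_len(L), function(l) {
      sel <- okm; sel[l, ] <- FALSE; sel[, l] <- FALSE
      if (!any(sel)) return(NA_real_)
      wj <- S[sel]
      sum(wj * (r2[sel] - ld_ne_bias(S[sel]))) / sum(wj)
    }, numeric(1))
    drifts <- drifts[is.finite(drifts)]
    m <- length(drifts)
    if (m > 2) {
      jbar <- mean(drifts)
      se <- sqrt((m - 1) / m * sum((drifts - jbar)^2))
      lo_drift <- r2_drift - 1.96 * se
      hi_drift <- r2_drift + 1.96 * se
      # Ne is decreasing in the drift signal
      ci <- c(ld_ne_transform(hi_drift), ld_ne_transform(lo_drift))
    }
  }
  list(ne = ne, r2_mean = r2_mean, r2_drift = r2_drift,
       n_loci = L, n_pairs = sum(ok),
       s_harmonic = 1 / mean(1 / S[ok]), ci = ci)
}
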