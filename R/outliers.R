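# Outlier-locus detection: a trimmed chi-square scan on per-locus Fst and a
# principal-component regression scan, plus import of external per-locus
# results and the consensus/neutral-set bookkeeping.

#' Per-locus differentiation statistic without sample-size correction
#'
#' The raw ratio of the weighted among-group variance of allele frequencies
#' to the total allele-frequency variance,
#' `Fhat = s^2 / (pbar (1 - pbar))` with
#' `s^2 = sum(n_i (p_i - pbar)^2) / ((r - 1) nbar)`. Omitting the
#' finite-sample correction keeps the null distribution close to a scaled
#' chi-square with about `r - 1` degrees of freedom, which is what the
#' trimmed-distribution fit of [trimmed_chi2_scan()] requires. Monomorphic
#' loci get `NA`.
#'
#' @param g A [geno_matrix()].
#' @param map A [pop_map()].
#' @param level Grouping level (default `"region"`).
#' @return List with `fst` (per-locus statistic), `he` (total expected
#'   heterozygosity `2 pbar (1 - pbar)`), and `n_groups`.
#' @export
per_locus_fst_uncorrected <- function(g, map, level = "region") {
  labels <- as.factor(map_level(map, g$sample_ids, level))
  r <- nlevels(labels)
  if (r < 2) {
    stop_pstfst("at least two groups are required", "pstfst_invalid_input")
  }
  d <- g$dosage
  L <- ncol(d)
  n <- matrix(0, r, L); p <- matrix(NA_real_, r, L)
  for (i in seq_len(r)) {
    di <- d[labels == levels(labels)[i], , drop = FALSE]
    n[i, ] <- colSums(!is.na(di))
    p[i, ] <- ifelse(n[i, ] > 0, colSums(di, na.rm = TRUE) / (2 * n[i, ]), NA)
  }
  usable <- colSums(n > 0) == r
  nbar <- colSums(n) / r
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  he <- 2 * pbar * (1 - pbar)
  fst <- ifelse(usable & pbar > 0 & pbar < 1, s2 / (pbar * (1 - pbar)),
                NA_real_)
  list(fst = stats::setNames(fst, g$locus_meta$id),
       he = stats::setNames(he, g$locus_meta$id), n_groups = r)
}

#' Trimmed chi-square outlier scan
#'
#' Fits a scaled chi-square distribution (mean `Fbar`, degrees of freedom
#' `k`) to the trim-interior of the per-locus differentiation statistics by
#' truncated maximum likelihood, then assigns right-tail p-values to every
#' locus and Benjamini-Hochberg q-values. Loci with total expected
#' heterozygosity below `he_min` are excluded from both the fit and the
#' calls, since low-diversity loci have erratic differentiation estimates.
#'
#' @param stats Per-locus statistic vector, e.g.
#'   [per_locus_fst_uncorrected()]`$fst`.
#' @param he Per-locus total expected heterozygosity (same length).
#' @param trim_low,trim_high Lower/upper trim fractions for the fit
#'   (defaults 0.05 each).
#' @param he_min Heterozygosity floor (default 0.10).
#' @param df_init Starting degrees of freedom for the fit (e.g. number of
#'   groups minus 1).
#' @param q_threshold Flagging threshold on the q-value (default 0.05).
#' @return List with `p`, `q`, `flag` (per locus; `NA` where excluded),
#'   `fbar`, `df`, `n_fit`.
#' @export
trimmed_chi2_scan <- function(stats, he = NULL, trim_low = 0.05,
                              trim_high = 0.05, he_min = 0.10,
                              df_init = 5, q_threshold = 0.05) {
  check_number(trim_low, "trim_low", 0, 0.5, strict_upper = TRUE)
  check_number(trim_high, "trim_high", 0, 0.5, strict_upper = TRUE)
  L <- length(stats)
  usable <- is.finite(stats) & stats > 0
  if (!is.null(he)) usable <- usable & is.finite(he) & he >= he_min
  x_all <- stats[usable]
  if (length(x_all) < 2 || stats::sd(x_all) == 0) {
    stop_pstfst("degenerate statistic vector: no spread to fit",
                "pstfst_fit_error")
  }
  if (length(x_all) < 50) {
    warning("fewer than 50 usable loci; the trimmed fit will be unstable")
  }
  qs <- stats::quantile(x_all, c(trim_low, 1 - trim_high), names = FALSE)
  interior <- x_all[x_all >= qs[1] & x_all <= qs[2]]
  n_fit <- length(interior)

  # truncated scaled-chi-square likelihood: x ~ (Fbar/k) * chisq(k) on
  # [qs[1], qs[2]]
  negll <- function(par) {
    fbar <- exp(par[1]); k <- exp(par[2])
    z <- interior * k / fbar
    mass <- stats::pchisq(qs[2] * k / fbar, k) -
      stats::pchisq(qs[1] * k / fbar, k)
    if (!is.finite(mass) || mass <= 0) return(1e10)
    -(sum(stats::dchisq(z, k, log = TRUE)) + n_fit * log(k / fbar) -
        n_fit * log(mass))
  }
  fit <- stats::optim(c(log(mean(interior)), log(df_init)), negll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  fbar <- exp(fit$par[1]); df <- exp(fit$par[2])

  p <- rep(NA_real_, L)
  p[usable] <- stats::pchisq(stats[usable] * df / fbar, df,
                             lower.tail = FALSE)
  q <- rep(NA_real_, L)
  q[usable] <- stats::p.adjust(p[usable], method = "BH")
  flag <- !is.na(q) & q < q_threshold
  flag[!usable] <- NA
  names(p) <- names(q) <- names(flag) <- names(stats)
  list(p = p, q = q, flag = flag, fbar = fbar, df = df, n_fit = n_fit)
}

#' Principal-component regression outlier scan
#'
#' Mean-imputes missing dosages, centres and scales each locus, computes
#' the first `K` principal components over individuals, regresses every
#' locus on those components, and scores loci by the Mahalanobis distance
#' of their `K` regression z-scores (robust covariance). Distances are
#' rescaled by a genomic inflation factor (median distance over the
#' chi-square median with `K` degrees of freedom) before conversion to
#' p-values, then Benjamini-Hochberg q-values.
#'
#' @param g A [geno_matrix()].
#' @param K Number of principal components (>= 1 and < min(individuals,
#'   loci)); a natural choice is the number of sampled groups minus 1.
#' @param q_threshold Flagging threshold on the q-value (default 0.05).
#' @return List with `p`, `q`, `flag` (per locus; constant loci `NA`),
#'   `gif`, `singular_values` (for a scree check), `K`.
#' @export
pc_regression_scan <- function(g, K, q_threshold = 0.05) {
  d <- g$dosage
  n <- nrow(d); L <- ncol(d)
  check_count(K, "K")
  if (K >= min(n, L)) {
    stop_pstfst("K must be smaller than both the number of individuals and loci",
                "pstfst_invalid_parameter")
  }
  mu <- colMeans(d, na.rm = TRUE)
  X <- d
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- mu[((idx - 1) %/% n) + 1]
  sds <- apply(X, 2, stats::sd)
  variable <- is.finite(sds) & sds > 0
  Xs <- scale(X[, variable, drop = FALSE])
  sv <- svd(Xs, nu = K, nv = 0)
  scores <- sv$u                      # orthonormal n x K
  # regression of each (scaled) locus on the K orthonormal score vectors
  beta <- crossprod(scores, Xs)       # K x L'
  rss <- colSums(Xs^2) - colSums(beta^2)
  dfree <- n - K - 1
  sigma <- sqrt(pmax(rss, 0) / dfree)
  z <- t(beta) / sigma                # L' x K
  z[!is.finite(z)] <- 0
  rob <- MASS::cov.rob(z)
  d2 <- stats::mahalanobis(z, rob$center, rob$cov)
  gif <- stats::median(d2) / stats::qchisq(0.5, K)
  p_v <- stats::pchisq(d2 / gif, K, lower.tail = FALSE)
  p <- rep(NA_real_, L)
  p[variable] <- p_v
  q <- rep(NA_real_, L)
  q[variable] <- stats::p.adjust(p_v, method = "BH")
  flag <- !is.na(q) & q < q_threshold
  flag[!variable] <- NA
  names(p) <- names(q) <- names(flag) <- g$locus_meta$id
  list(p = p, q = q, flag = flag, gif = gif,
       singular_values = sv$d, K = K)
}

#' Import an external per-locus outlier scan
#'
#' Reads a tab-separated file with columns `id`, `value`, `flag`
#' (flag 0/1 or TRUE/FALSE) produced by an external scan (for example a
#' Bayesian per-locus selection test) and returns flags aligned to the
#' given locus ids.
#'
#' @param path Path to the TSV file.
#' @param locus_ids Character vector of locus ids the flags must match.
#' @param method_label Name under which the method is reported.
#' @return List with `flag` (logical per locus, named), `value`, and
#'   `method_label`.
#' @export
import_external_scan <- function(path, locus_ids, method_label = "external") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("id", "flag") %in% names(df))) {
    stop_pstfst("external scan file needs columns `id` and `flag`",
                "pstfst_io_error")
  }
  if (nrow(df) == 0) {
    warning("external scan file is empty: zero flags imported")
    flag <- stats::setNames(rep(FALSE, length(locus_ids)), locus_ids)
    return(list(flag = flag, value = NULL, method_label = method_label))
  }
  unmatched <- setdiff(df$id, locus_ids)
  if (length(unmatched)) {
    stop_pstfst(paste0("external scan ids not present in the data: ",
                       paste(utils::head(unmatched, 10), collapse = ", ")),
                "pstfst_io_error")
  }
  flag <- stats::setNames(rep(FALSE, length(locus_ids)), locus_ids)
  flag[df$id] <- as.logical(df$flag)
  value <- NULL
  if ("value" %in% names(df)) {
    value <- stats::setNames(rep(NA_real_, length(locus_ids)), locus_ids)
    value[df$id] <- as.numeric(df$value)
  }
  list(flag = flag, value = value, method_label = method_label)
}

#' Run the outlier scans and assemble a per-locus report
#'
#' @param g A [geno_matrix()].
#' @param map A [pop_map()].
#' @param level Grouping level driving differentiation (default `"region"`).
#' @param K Components for the PC scan; default number of groups minus 1.
#' @param trim_low,trim_high,he_min Passed to [trimmed_chi2_scan()].
#' @param q_threshold Flagging threshold for both scans.
#' @param external Optional list of results from [import_external_scan()].
#' @return An object of class `outlier_report`: a data frame with one row
#'   per locus (`id`, `fst_uncorrected`, `he`, per-method q/flag columns,
#'   `consensus_tier`) plus attributes `methods` and fit diagnostics.
#' @export
scan_outliers <- function(g, map, level = "region", K = NULL,
                          trim_low = 0.05, trim_high = 0.05, he_min = 0.10,
                          q_threshold = 0.05, external = NULL) {
  pl <- per_locus_fst_uncorrected(g, map, level)
  if (is.null(K)) K <- max(1L, pl$n_groups - 1L)
  tc <- trimmed_chi2_scan(pl$fst, pl$he, trim_low = trim_low,
                          trim_high = trim_high, he_min = he_min,
                          df_init = pl$n_groups - 1, q_threshold = q_threshold)
  pc <- pc_regression_scan(g, K, q_threshold = q_threshold)
  report <- data.frame(
    id = g$locus_meta$id,
    fst_uncorrected = unname(pl$fst),
    he = unname(pl$he),
    trimmed_chi2_q = unname(tc$q),
    trimmed_chi2_flag = unname(tc$flag),
    pc_q = unname(pc$q),
    pc_flag = unname(pc$flag),
    stringsAsFactors = FALSE
  )
  methods <- c("trimmed_chi2", "pc")
  if (!is.null(external)) {
    if (!is.null(external$method_label)) external <- list(external)
    for (ext in external) {
      col <- paste0(ext$method_label, "_flag")
      report[[col]] <- unname(ext$flag[report$id])
      methods <- c(methods, ext$method_label)
    }
  }
  attr(report, "methods") <- methods
  attr(report, "trimmed_fit") <- list(fbar = tc$fbar, df = tc$df,
                                      n_fit = tc$n_fit)
  attr(report, "pc_fit") <- list(gif = pc$gif, K = pc$K,
                                 singular_values = pc$singular_values)
  class(report) <- c("outlier_report", "data.frame")
  report
}

#' Consensus outlier list and complementary neutral set
#'
#' Combines per-method flags into a consensus under the chosen rule and
#' returns the complementary neutral locus set used for drift-only
#' statistics. The default rule `"any"` excludes every locus flagged by at
#' least one method.
#'
#' @param report An [scan_outliers()] report (or any data frame with
#'   `id` and `*_flag` columns).
#' @param rule `"any"`, `"at-least-2"`, or `"all"`.
#' @return List with `consensus` (outlier locus ids), `neutral_set`
#'   (the complement), and `tiers` (per-locus factor: `all-methods`,
#'   `two-methods`, `one-method`, `none`).
#' @export
consensus_and_neutral_set <- function(report,
                                      rule = c("any", "at-least-2", "all")) {
  rule <- match.arg(rule)
  flag_cols <- grep("_flag$", names(report), value = TRUE)
  if (!length(flag_cols)) {
    stop_pstfst("report contains no method flag columns",
                "pstfst_invalid_input")
  }
  fm <- as.matrix(report[flag_cols])
  fm[is.na(fm)] <- FALSE
  n_methods <- length(flag_cols)
  hits <- rowSums(fm)
  tiers <- cut(hits, breaks = c(-0.5, 0.5, 1.5, if (n_methods > 2) 2.5,
                                n_methods + 0.5),
               labels = c("none", "one-method",
                          if (n_methods > 2) "two-methods",
                          "all-methods"))
  if (n_methods == 2) {
    levels(tiers) <- c("none", "one-method", "all-methods")
  }
  min_hits <- switch(rule, any = 1L, `at-least-2` = 2L, all = n_methods)
  consensus <- report$id[hits >= min_hits]
  list(consensus = consensus,
       neutral_set = setdiff(report$id, consensus),
       tiers = stats::setNames(tiers, report$id))
}
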