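# Independent oracles and fixture builders shared across tests.

# quick geno_matrix from a dosage matrix (rows = individuals)
make_geno <- function(dosage, ids = NULL) {
  n <- nrow(dosage); L <- ncol(dosage)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(n))
  meta <- data.frame(chrom = "chr1", pos = seq_len(L) * 10L,
                     id = sprintf("L%03d", seq_len(L)),
                     ref = "A", alt = "T", multiallelic = FALSE,
                     stringsAsFactors = FALSE)
  geno_matrix(dosage, meta, ids)
}

# two-population map over a set of individual ids
make_map2 <- function(ids, split = length(ids) %/% 2) {
  pop_map(data.frame(
    individual = ids,
    population = rep(c("popA", "popB"), c(split, length(ids) - split)),
    region = rep(c("A", "B"), c(split, length(ids) - split)),
    range = rep(c("native", "non-native"), c(split, length(ids) - split)),
    stringsAsFactors = FALSE))
}

# Independent Weir-Cockerham theta via the nested allele-level ANOVA
# route: alleles within individuals within populations. The variance
# components follow from the mean squares (a from MSP, b from MSI, c =
# MSG), an algebraically different derivation from the frequency-based
# formulas used by the package.
anova_theta <- function(dosage, pops) {
  num <- den <- 0
  for (l in seq_len(ncol(dosage))) {
    d <- dosage[, l]
    keep <- !is.na(d)
    if (!any(keep)) next
    d <- d[keep]; pp <- pops[keep]
    if (length(unique(pp)) < 2) next
    # allele table: two rows per individual
    x <- c(ifelse(d >= 1, 1, 0), ifelse(d == 2, 1, 0))
    ind <- rep(seq_along(d), 2)
    pop <- rep(pp, 2)
    n_i <- as.numeric(table(pp))          # individuals per pop
    r <- length(n_i)
    ntot <- sum(n_i)
    if (mean(n_i) <= 1) next
    m_ind <- tapply(x, ind, mean)
    m_pop <- tapply(x, pop, mean)
    m_all <- sum(n_i * m_pop[names(table(pp))]) / ntot
    ssg <- sum((x - m_ind[as.character(ind)])^2)
    ssi <- sum(2 * (m_ind - m_pop[as.character(pp)])^2)
    ssp <- sum(2 * n_i * (m_pop[names(table(pp))] - m_all)^2)
    msg <- ssg / ntot
    msi <- ssi / (ntot - r)
    msp <- ssp / (r - 1)
    nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
    a <- (msp - msi) / (2 * nc)
    b <- (msi - msg) / 2
    cc <- msg
    if (is.finite(a + b + cc)) {
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# exhaustive rarefaction oracle: mean number of distinct alleles over all
# subsets of size g of the observed allele copies
enum_ar <- function(allele_counts, g) {
  alleles <- rep(seq_along(allele_counts), allele_counts)
  subs <- utils::combn(length(alleles), g)
  mean(apply(subs, 2, function(ix) length(unique(alleles[ix]))))
}

# Wright-Fisher forward simulation: `ne` diploids, `n_loci` unlinked loci,
# random union of gametes with free recombination, `n_gen` generations;
# returns the dosage matrix of `n_sample` sampled individuals
wf_sim <- function(ne, n_loci, n_gen, n_sample, p0 = NULL) {
  if (is.null(p0)) p0 <- stats::runif(n_loci, 0.3, 0.7)
  h1 <- matrix(stats::rbinom(ne * n_loci, 1, rep(p0, each = ne)), ne, n_loci)
  h2 <- matrix(stats::rbinom(ne * n_loci, 1, rep(p0, each = ne)), ne, n_loci)
  for (g in seq_len(n_gen)) {
    gamete <- function() {
      par <- sample.int(ne, ne, replace = TRUE)
      pick <- matrix(stats::runif(ne * n_loci) < 0.5, ne, n_loci)
      ifelse(pick, h1[par, ], h2[par, ])
    }
    n1 <- gamete(); n2 <- gamete()
    h1 <- n1; h2 <- n2
  }
  idx <- sample.int(ne, n_sample)
  h1[idx, , drop = FALSE] + h2[idx, , drop = FALSE]
}

# ten-site toy VCF with hand-constructed filter outcomes; returns the path
# and the expected survivor ids.
# Design: 2 populations of 10 individuals each (40 alleles total).
#  s01 clean, MAF 0.30                      -> survives
#  s02 triallelic ALT "T,G"                 -> removed (biallelic)
#  s03 indel ALT "TT"                       -> removed (indel)
#  s04 pop A call rate 0.8                  -> removed (call rate)
#  s05 call rate exactly 0.9 in both pops   -> survives (threshold inclusive)
#  s06 MAF exactly 0.05 (2/40)              -> removed (strict MAF)
#  s07 MAF 0.075 (3/40)                     -> survives
#  s08 monomorphic                          -> removed (MAF)
#  s09 pop B entirely missing               -> removed (call rate)
#  s10 one missing call in pop A, MAF high  -> survives
write_toy_filter_vcf <- function(dir = tempdir()) {
  n <- 20
  gt <- function(dos) c("0/0", "0/1", "1/1")[dos + 1]
  rows <- list()
  site <- function(id, ref, alt, calls) {
    paste(c("1", as.character(length(rows) + 1), id, ref, alt, ".", "PASS",
            ".", "GT", calls), collapse = "\t")
  }
  full <- function(n_alt) gt(c(rep(1, n_alt), rep(0, n - n_alt)))
  rows[[1]] <- site("s01", "A", "T", gt(rep(c(0, 1, 2, 0), 5)))
  rows[[2]] <- site("s02", "A", "T,G", full(4))
  rows[[3]] <- site("s03", "A", "TT", full(4))
  c4 <- full(8); c4[1:2] <- "./."                      # pop A 8/10 called
  rows[[4]] <- site("s04", "C", "G", c4)
  c5 <- full(8); c5[1] <- "./."; c5[11] <- "./."       # 9/10 in each pop
  rows[[5]] <- site("s05", "C", "G", c5)
  rows[[6]] <- site("s06", "A", "G", gt(c(1, rep(0, 9), 1, rep(0, 9))))
  rows[[7]] <- site("s07", "A", "G", gt(c(1, 1, 1, rep(0, 17))))
  rows[[8]] <- site("s08", "A", "C", gt(rep(0, 20)))
  c9 <- full(8); c9[11:20] <- "./."                    # pop B absent
  rows[[9]] <- site("s09", "T", "A", c9)
  c10 <- gt(rep(c(2, 1, 0, 0), 5)); c10[2] <- "./."
  rows[[10]] <- site("s10", "T", "C", c10)
  ids <- c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10))
  path <- file.path(dir, "toy_filter.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"),
    unlist(rows)), path)
  list(path = path,
       map = make_map2(ids, 10),
       survivors = c("s01", "s05", "s07", "s10"))
}

# reorder loci of a geno_matrix (internal helper exposed for order tests)
subset_geno_for_test <- function(g, loci) {
  pstfst:::subset_geno(g, loci = loci)
}
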