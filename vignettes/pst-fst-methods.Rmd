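---
title: "Testing trait divergence against neutral expectations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing trait divergence against neutral expectations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pstfst)
```

## The question the package answers

When a species is sampled across several geographic regions and its
offspring are raised together in one glasshouse, trait differences among
regions reflect the origin of the seed rather than the environment of
measurement. The question is then whether those differences are *larger*
than genetic drift alone would produce. The standard yardstick is the
neutral molecular differentiation among the same groups: if the phenotypic
divergence index Pst clearly exceeds the SNP-based Fst, drift is an
unlikely sole explanation and divergent selection on the trait is implied;
if Pst falls clearly below Fst, stabilizing selection is implied.

Pst is the phenotypic analogue of Qst,

$$P_{ST} = \frac{\sigma^2_B}{\sigma^2_B + 2 h^2 \sigma^2_W},$$

where $\sigma^2_B$ is the trait variance among the compared groups,
$\sigma^2_W$ the variance within them, and $h^2$ the assumed heritability.
Because common-garden data provide no pedigree, $h^2 = 1$ is assumed by
default, the conventional conservative choice for this index; `pst_config(h2 = )`
exposes it. Pst confounds genetic and residual maternal/plastic
divergence, which is an interpretive caveat, not something the model can
remove.

## The hierarchical model and its sampler

Trait values are modelled as

$$y_i = \mu + a_{u(i)} + b_{p(i)} + e_i,\qquad
a \sim N(0, \sigma^2_B),\; b \sim N(0, \sigma^2_P),\;
e \sim N(0, \sigma^2_e),$$

with `u` the top-level unit of the comparison (a pair of regions, or the
native/non-native range split) and `p` the population. All full
conditionals are conjugate, so `gibbs_fit()` is a pure Gibbs sampler:
normal updates for $\mu$, $a$, $b$ and inverse-gamma updates for the three
variances. Five chains of 50,000 retained iterations after a burn-in of
1000 are the defaults, with overdispersed starts (each chain scales
method-of-moments variance estimates log-uniformly over $[10^{-2},
10^2]$), no thinning, and the Gelman-Rubin $\hat R$ reported per variance
component. Posterior draws of Pst are obtained by applying the formula to
each draw; the within-group variance is $\sigma^2_P + \sigma^2_e$ by
default (`sigma_w_convention = "residual-plus-population"`), since for a
two-region or two-range comparison all phenotypic variance inside the
compared units is "within"; a residual-only convention is one switch away.
Both conventions coincide when $\sigma^2_P$ is negligible, and neither can
be singled out from published summary tables alone.

The decision rule follows the credibility interval of the difference: with
interval mass 0.975 (quantiles 0.0125 and 0.9875 — the literature this
index comes from prints "97.5% CI", which may be shorthand for a 95%
interval bounded at the 2.5/97.5 percentiles; the mass is one config flag,
`interval_mass`, if the other reading is preferred), a trait is classified
*divergent* if the interval of $P_{ST} - F_{ST}$ lies entirely above zero,
*stabilizing* entirely below, and *drift-consistent* otherwise. The
subtracted Fst is a scalar mean by default; a vector of bootstrap Fst
draws can be supplied instead, in which case each Pst draw is paired with
a resampled Fst draw.

### Priors: why not the historical vague inverse-gamma

The WinBUGS-era convention puts $IG(0.001, 0.001)$ on each variance. For
$\sigma^2_P$ and $\sigma^2_e$, which are informed by tens of populations
and hundreds of individuals, the prior is immaterial. For $\sigma^2_B$ it
is not: every comparison in this design has exactly **two** top-level
units, so the between-unit variance is informed by two group effects, the
posterior retains the prior's heavy upper tail (its shape parameter is
about 1), and posterior-mean Pst is pushed far toward 1. In
parameter-recovery simulations at a two-unit design this inflates the
replicate-average posterior-mean Pst to roughly twice its true value.

The default prior is therefore a half-Cauchy on each standard deviation —
the standard weakly-informative alternative for group-level variances with
few groups — implemented through its inverse-gamma scale-mixture
representation so that the sampler remains pure Gibbs. The scale is
$\sqrt{\mathrm{var}(y)/3}$ per component: the standard deviation each
component would have if the three components split the observed trait
variance evenly. Tying the scale to the data keeps Pst invariant under
affine rescaling of the trait. The historical prior remains available via
`pst_config(prior = "inverse-gamma")` for comparability. A
prior-sensitivity sweep over candidate scales (from the full trait
standard deviation down to a quarter of it, and half-normal alternatives)
showed the decision rule's null calibration is insensitive to the choice —
false "divergent" calls were not observed under any candidate — while
recovery bias varies; the equal-split scale sits at the calibrated middle
of that sweep.

With only two units the posterior for $\sigma^2_B$ is intrinsically wide:
the identifiable signal is a single between-unit contrast. The test suite
therefore asserts recovery of the *replicate-average* posterior mean
across many simulated fixtures, and interval-based calibration of the
decision rule, rather than tight recovery on any single fixture — no prior
can deliver the latter.

## Neutral differentiation

`wc_fst()` implements the Weir-Cockerham (1984) variance-component
estimator for diploid biallelic loci with unequal, locus-varying sample
sizes: per-locus among-group ($a$), among-individual ($b$) and
within-individual ($c$) components, combined as the ratio of sums
$\hat\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)$ over loci with
positive total variance. Pairwise comparisons treat the two regions (or
the two ranges) as the two populations of the model. Confidence intervals
are percentile bootstrap over loci (1000 replicates by default; the
interval method is a package convention, as published tables state only
"95% CI"). The test suite checks the estimator against an independent
implementation that takes the allele-level nested-ANOVA route to the same
components, and against Balding-Nichols simulations whose expected theta
is the configured drift parameter.

Fst values handed to the Pst stage are computed on the **neutral locus
set** — the complement of the outlier consensus — mirroring standard
practice; `pipeline_config(neutral_only = FALSE)` is the explicit
override.

## Outlier scans and the neutral set

Two scans are re-implemented behind `scan_outliers()`:

* **Trimmed chi-square scan.** A per-locus differentiation statistic
  without finite-sample correction,
  $\hat F_l = s^2_l / (\bar p_l (1 - \bar p_l))$ with $s^2$ the weighted
  among-group variance of allele frequencies, is fitted to a scaled
  chi-square distribution (mean $\bar F$, degrees of freedom $k$) by
  maximum likelihood on the trim interior (default 5% trimmed from each
  tail), with the likelihood truncated at the trim cutpoints. Right-tail
  p-values then flow through Benjamini-Hochberg to q-values; loci with
  total expected heterozygosity below 0.10 are excluded from both fit and
  calls (defaults follow the published trimmed-likelihood method).
* **Principal-component regression scan.** Dosages are mean-imputed,
  centred and scaled; each locus is regressed on the first $K$ principal
  components over individuals ($K$ defaults to the number of groups minus
  one, with singular values returned for a scree check); the Mahalanobis
  distance of the $K$ regression z-scores (robust covariance) is rescaled
  by a genomic inflation factor (median distance over the chi-square
  median) and converted to chi-square p-values, then q-values.

Benjamini-Hochberg is used for both scans because it is parameter-free;
the original tools differ here (one uses Storey's q-values) and a config
hook is left for that option. The consensus rule defaults to `"any"` —
a locus flagged by at least one method is excluded from the neutral set,
which is the arithmetic implied by published neutral-set sizes. Externally
computed per-locus results (for example from a Bayesian
reversible-jump scan, which is out of scope to re-implement) can be
merged through `import_external_scan()` as a third method.

Calibration simulations in the test suite bound the null flag rate at 1%
(q < 0.05) and require 80%/70% power for the two scans when 2% of loci
carry a tenfold-elevated drift parameter at the generator's default
background (F = 0.05, the middle of the differentiation range the package
is designed for). At the bottom of that range (F = 0.02) a tenfold spike
is intrinsically harder to separate from sampling noise with six groups of
24 and measured power drops to roughly 55-65%; users scanning weakly
structured data should expect that.

## Diversity statistics and effective population size

Per-group observed and expected heterozygosity are per-locus fractions and
$2\hat p(1-\hat p)$ respectively, averaged over loci polymorphic within
the group (the reporting convention of the tables these statistics usually
appear in; an all-loci mean and an unbiased $2n/(2n-1)$ variant are
switches). $F_{IS} = 1 - \sum_l Ho_l / \sum_l He_l$ is a ratio of sums
over polymorphic loci. Allelic richness uses hypergeometric rarefaction to
a common allele-sample size, defaulting to the largest size every group
supports; the implementation is checked against exhaustive subsample
enumeration.

`ld_ne()` estimates effective population size from inter-locus linkage
disequilibrium: Burrows composite disequilibrium between every locus pair
from pairwise-complete genotypes (with the conventional $S/(S-1)$
small-sample factor), squared allelic correlation
$\hat r^2 = \hat\Delta^2 / (p(1-p)q(1-q))$, a sample-size bias adjustment
($1/S + 3.19/S^2$ for $S \ge 30$, $0.0018 + 0.907/S + 4.44/S^2$ below),
and the random-mating drift inversion
$N_e = (1/3 + \sqrt{1/9 - 2.76 \hat r^2_{drift}})/(2 \hat r^2_{drift})$.
A non-positive drift signal reports $N_e = \infty$, as is standard. Loci
below a minor-allele-frequency floor (default 0.05) are excluded; an
optional delete-one-locus jackknife gives an interval. The estimator is
validated against Wright-Fisher forward simulations (true $N_e = 50$,
median estimate within a factor of two) and no-drift fixtures (estimates
effectively infinite).

## The synthetic-data generator

`simulate_genotypes()` emulates the sampling design of a range-wide
common-garden study: six regions, several populations per region, a
balanced two dozen individuals per region, and ~2000 anonymous biallelic
SNPs. Allele frequencies follow a two-level Balding-Nichols model: a
region-level Beta draw with drift parameter `F_neutral` (defaults to 0.05,
mid-range of the 0.02-0.09 differentiation typical of such data) and a
second population-level draw with a small `F_pop` (default 0.01,
reflecting weak within-region substructure), so both region-level and
population-level statistics are exercised. Genotypes are binomial draws
from population frequencies, missingness is completely at random (no
mechanism being published for ddRAD missingness), and an optional minority
of loci receives an elevated drift parameter to stand in for selection —
enough to exercise outlier scans, without modelling explicit selection
coefficients. `simulate_traits()` draws Gaussian traits from exactly the
hierarchical model the sampler fits, recording drawn effects and the true
Pst implied by the configured variances. Fixtures are balanced by default;
published designs rarely report post-attrition per-population sizes, and
balance keeps truth values exact.

What the generator does *not* emulate — linkage between loci, genotyping
error, non-Gaussian traits (capitula counts are counts), maternal effects,
isolation-by-distance — bounds what passing tests show about real data:
they validate the estimators and the decision rule under the stated model,
not robustness to these violations.

## Numerical choices and degenerate inputs

* Filtering order is fixed (biallelic/indel, per-population call rate,
  global MAF) and idempotent; the call-rate threshold is inclusive
  ($\ge 0.9$) and the MAF threshold strict ($> 0.05$), matching the
  command-line flag semantics these rules are usually expressed in. The
  published order of filter application is not stated anywhere we know of;
  survivor sets can differ slightly under reorderings, so the fixed order
  is a documented convention.
* Monomorphic loci: excluded from Fst sums (zero total variance), from
  the trimmed fit (undefined statistic), and from polymorphic-only
  diversity means; allelic richness reports 1.
* Constant traits: the sampler warns and collapses the variances toward
  the prior floor rather than diverging.
* All randomness flows from a single integer seed through a fixed
  multiplicative derivation (`derive_seeds()`), so any stage can be rerun
  in isolation bit-for-bit.

## Problem sizes used by the test suite

The suite favours study-shaped but compact simulations: 2000-locus
fixtures for estimator recovery and scan calibration (20 and 3-5 seeded
replicates respectively), 50 replicate trait fixtures at the two-unit
recovery design, 100 reduced-scale replicates (120 individuals, 3 chains
of 1500 retained iterations) for the null calibration of the decision
rule, and 50 Wright-Fisher replicates for the LD-Ne oracle. These sizes
were chosen as the smallest at which the Monte-Carlo error of each check
is comfortably below the tolerance it asserts.

## Known limitations

* Pst is not Qst: without a breeding design the between-group variance
  includes any persistent maternal or epigenetic component, and $h^2 = 1$
  makes the test conservative only under the usual assumptions.
* Two-unit comparisons leave $\sigma^2_B$ prior-sensitive; the package
  reports full posteriors and $\hat R$, and the vignette's prior section
  documents the default's behaviour, but no prior manufactures
  information that two group effects do not contain.
* The LD-Ne bias adjustment is an empirical curve fitted for a particular
  estimator family; residual bias at small samples is visible in the
  factor-two tolerance of the recovery check.
* BayeScan-style posterior-probability scans are supported only through
  result import, not re-implementation.
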