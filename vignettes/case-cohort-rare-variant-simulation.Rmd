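---
title: "Simulating and evaluating rare-variant tests under a case-cohort design"
author: "ccrvsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating rare-variant tests under a case-cohort design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrvsim)
```

## The problem

Targeted and exome sequencing studies often cannot afford to sequence a
whole cohort. A common compromise is the *case-cohort* design: sequence a
random subcohort, then top it up with individuals chosen from the extremes
of one or more quantitative traits. The resulting sample is deliberately
non-representative — its phenotype distribution is heavy-tailed by
construction, and when the enrichment traits are correlated, the
distortions interact. Aggregate rare-variant tests (burden, kernel, and
score statistics) were developed and validated mostly for random samples,
so their operating characteristics under this design need to be checked,
not assumed.

`ccrvsim` provides the full simulation loop needed for that check:
correlated-trait generation, the two-stage sampler, synthetic
targeted-region genotypes, causal-effect injection, four aggregate tests
implemented from their defining formulas, and replicate engines that turn
p-values into empirical type I error (with binomial confidence intervals)
and raw or calibration-adjusted power.

## Correlated traits from a signed doubling tree

Traits are built from shared Student-t components. Starting from one
component, each of `k` iterations draws a single new t value per
individual and doubles the trait list: first half = previous traits plus
the new component, second half = their negatives plus the new component.
After `k = 4` iterations there are 16 traits, each the signed sum of the
same 5 components, and the population correlation between two traits is
exactly the dot product of their sign rows divided by 5. The first 11
traits realise the target correlation matrix used throughout the package,
with all off-diagonal values in $\{\pm 0.2, \pm 0.6\}$:

```{r signs}
S <- build_sign_matrix(4)
implied_trait_correlation(S)[1:4, 1:4]
```

Two details of this construction are worth making explicit, because the
verbal description admits alternatives:

* **One shared new component per iteration.** If instead every new trait
  received its own independent t draw, pairwise correlations of
  $\pm 0.8$ would appear, which the target matrix does not contain. The
  shared-component reading is the only one consistent with the target.
* **Ordering `[+previous, −previous]`, parents in order.** This
  reproduces the target matrix row for row, so trait indices (which trait
  is anticorrelated with which) carry over unchanged.

With `df = 15` each trait has variance $5 \times 15/13 \approx 5.77$.
Traits are deliberately *not* standardised: genetic effects are added to
the raw scale, all four tests are location/scale equivariant, and scaling
would only relabel the explained-variance bookkeeping. Component draws are
consumed in individual-major order from one seeded generator, so a run is
reproducible from its seed alone.

## The two-stage sampler

`sample_case_cohort()` first draws the random subcohort (default 504 from
12,000), then walks the traits in a fixed order, ranking the
*not-yet-selected* individuals on each trait and taking the configured
number from the configured tail (default: the top 50 for traits 1–10, the
top 92 for trait 11 — 1,096 individuals in total, 592 of them extremes).
Exclusion means an individual is selected once, labelled by the first
trait that claimed it.

Choices the design description leaves open, fixed here and configurable:

* **Tail.** "Top" extremes are read as the upper tail; `tail = "lower"`
  and `tail = "both"` (largest absolute values) are available.
* **Which trait gets the larger extreme set.** The last trait processed
  (trait 11) by default.
* **Trait processing order** is index order; ties in trait values are
  broken by individual index. Both are arbitrary but must be fixed for
  reproducibility.

## Synthetic regions and filters

`sample_region_spec()` draws per-variant MAFs log-uniformly on
(5×10⁻⁴, 10⁻²). The log-uniform shape mimics the rare-heavy site-frequency
spectra of sequencing panels while keeping expected minor-allele counts
informative at the sample sizes used here; region presets span 3 to 257
variants, matching the spread of targeted-region sizes the package is
meant to emulate. High-risk flags (standing in for non-synonymous,
stop-gain and splicing annotations) are Bernoulli draws; per-variant
missing rates come from a Beta(1, 30) (mean ≈ 3%, occasionally above the
10% removal threshold, so the filter has something to do).

Genotypes are independent Binomial(2, MAF) dosages — Hardy–Weinberg, no
linkage disequilibrium. Real targeted regions carry LD, but the design
provides no LD model to copy; independence is the testable default, and
correlated-haplotype generation can be plugged in by constructing
`genotype_region` objects from any dosage matrix.

`filter_variants()` keeps variants with estimated MAF strictly below 1%
and missing fraction at most 10%, and additionally drops monomorphic
variants (estimated MAF exactly 0): MAF-based weights are undefined for
them and they carry no information. Missing dosages are scored as 0 by
every test *after* this filter — a common collapsing-test convention.

What passing tests on these synthetic regions do **not** show: behaviour
under LD, under population stratification, or under informative
missingness. The generator makes none of those, by design.

## Causal models

Causal variants are chosen by four ordered rules that prioritise
high-risk variants while avoiding degenerate causal sets: regions under
10 variants are entirely causal; with fewer than 5 high-risk variants,
the high-risk set is topped up with a random 50% of the region's variant
count (regions of 10–100 variants) or 5% of the non-high-risk variants
(larger regions); with 5 or more high-risk variants, exactly the
high-risk set. Two readings were fixed here: the "additional 50%" is 50%
*of the region's total variant count*, drawn from non-high-risk variants
(the 5% rule names non-high-risk variants as its base, by contrast), and
fractional counts round half-up.

Effect sizes are $0.4\,|\log_{10}(\mathrm{MAF})|$ — 0.8 at MAF 1%, 1.2 at
0.1% — so rarer variants carry larger effects. In bidirectional mode the
first half of the causal variants (ceiling split, in variant order) stay
positive and the rest turn negative. Phenotypes under the alternative are
$y_p = y_0 + \sum_j \beta_j G_j$, and the explained variance is reported
as $R^2 = \mathrm{var}(\sum_j \beta_j G_j)/\mathrm{var}(y_p)$ on the
analyzed sample.

## The four tests

* **T1 (unweighted burden):** per-person count of rare variants carried;
  linear regression of the trait on this count, two-sided t-test.
* **MB (weighted burden):** per-person score
  $S_i = \sum_j G_{ij}/\hat w_j$ with
  $\hat w_j = \sqrt{n \hat p_j (1-\hat p_j)}$, then the same regression.
* **Kernel (SKAT-type):** $Q = \sum_j w_j S_j^2$ with per-variant scores
  $S_j = \sum_i G_{ij}(y_i - \hat\mu_{i0})$ from the covariate-only fit.
  The weight convention is the *squared* Beta(1, 25) density evaluated at
  the estimated MAF (the cited method's standard; the plain density is
  selectable via `squared = FALSE`). The null distribution is a mixture
  of 1-df chi-squares with the eigenvalues of the weighted,
  covariate-projected genotype cross-product.
* **Score test (Score-Seq-type):** collapses the region with a weight
  vector $\xi$ into $S_i = \xi' G_i$ and forms $T = U/\sqrt{V}$ from the
  printed score and variance formulas ($\hat\sigma^2$ with denominator
  $n$). $T$ is asymptotically standard normal; permutation p-values
  (permute the null residual vector, re-evaluate $|T|$, add-one
  correction) are available and were used for the calibration results
  below. Since $T$ is invariant to positive rescaling of $\xi$, the
  unidentified nuisance scaling of the defining regression drops out;
  the default is $\xi_j = 1$ (flat weights), with inverse
  Madsen–Browning weights selectable. All tests are two-sided, as effect
  direction is unknown by design.

### Numerical evaluation of the chi-square mixture

`pchisqmix()` evaluates $P(\sum_k \lambda_k \chi^2_1 > q)$ by Imhof's
characteristic-function inversion, truncating the integral where the
classical tail bound of the integrand drops below the tolerance
(default 10⁻⁶, tightened automatically to 10⁻¹⁰ when the first pass
returns below 10⁻⁴). Rank 1 short-circuits to the exact scaled
chi-square, rank 2 to an exact one-dimensional convolution (for two
eigenvalues the inversion integral oscillates over an impractically long
range), and the Liu–Tang–Zhang moment match serves as fallback when the
truncation point would be impractically large. Eigenvalues below
10⁻⁶ of the largest are discarded as rank noise.

## The replicate engines

Under the null, each replicate draws a *fresh* population of traits,
re-runs the sampler, and **randomly assigns** the selected phenotypes to
the fixed genotype rows. Both halves matter. Redrawing preserves the
selection-induced phenotype structure — the point of studying this
design. The random assignment is what makes genotype and phenotype
independent *per replicate*: the sampler emits extremes in rank order, so
pairing its output positionally with fixed genotype rows would hand the
largest phenotype to the same genotype row in every replicate, and
empirical rejection rates then reflect that one accidental pairing rather
than the null. (This surfaced in development as an impossible result — a
permutation test rejecting 8.7% at the 5% level — and is exactly why the
engine shuffles.) A cheaper `mode = "permute"` reuses one sample and
permutes its phenotypes, for smoke tests.

Power replicates add each region's fixed causal contribution to the
fresh null phenotype and record per-replicate $R^2$. Rejection is
$p \le \alpha$ (boundary included); confidence intervals are Wald
binomial by default with Clopper–Pearson selectable for small counts;
`adjusted_power()` rescales power by $\alpha/\widehat{\text{type I}}$ so
methods with unequal calibration can be compared.

One sequential RNG stream (from the grid's master seed) drives every
replicate including permutation sub-streams, so whole runs are
reproducible bit for bit.

## Problem sizes used in the shipped checks

The package's own test suite exercises the full design — population
12,000, sample 1,096, a 50-variant rare region, 2,000 null replicates
with 999-permutation score tests — for calibration, and a one-third-scale
design (population 4,000; subcohort 168 plus 17 extremes for ten traits
and 31 for the eleventh; 1,000 replicates) for the qualitative power
comparisons. These sizes give binomial standard errors around 0.005 at
$\alpha = 0.05$, small enough to detect meaningful miscalibration while
keeping the default suite quick; the full-scale 10,000-replicate,
many-region layout is a `replicate_grid()` call away.

```{r example, eval = FALSE}
traits <- generate_traits(12000, seed = 1)
samp <- sample_case_cohort(traits, sampling_config(seed = 2))
spec <- sample_region_spec(50, missing_beta = NULL, seed = 3)
region <- filter_variants(simulate_genotypes(spec, nrow(samp), seed = 4))
grid <- replicate_grid(2000, methods = c("t1", "mb", "skat", "scoreseq"),
                       seed = 5)
null_tab <- run_null_replicates(grid, region, n_perm = 999)
summarize_evaluation(null_tab)
```

## Known limitations

* No linkage disequilibrium, stratification, relatedness or informative
  missingness in the genotype generator; conclusions about those forces
  require plugging in real or coalescent genotypes (a VCF reader is
  included).
* The case-cohort sample is analyzed unweighted, as in the design being
  emulated; no pseudo-likelihood reweighting is implemented.
* Quantitative traits only; the score machinery extends to dichotomous
  traits, but that extension is out of scope here.
* The kernel test's analytic p-value assumes the mixture-of-chi-squares
  null; with very few carriers it tends to be conservative, which the
  calibration checks treat as acceptable (bounded above by nominal plus
  CI slack) rather than as equivalence to nominal.
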