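---
title: "Methods: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsynergy)
```

This vignette documents the statistical models behind each module, the
assumptions they rest on, every parameter default, and the numerical
choices that matter for reproducing results exactly.

## Median-effect dose-response and the combination index

`fit_median_effect()` fits the median-effect equation

$$ \frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m $$

by ordinary least squares of $\log_{10}(f_a/(1-f_a))$ on $\log_{10} D$:
the slope is $m$ and $D_m = 10^{-\mathrm{intercept}/m}$. Assumptions: a
monotone sigmoidal response fully described by $(m, D_m)$, and
log-odds-scale errors. Fraction-affected values are clipped to
$[10^{-4},\, 1-10^{-4}]$ before the transform (indices of clipped points
are reported in `$clipped`); replicate observations at a literally tied
dose are averaged on the transformed scale first so a replicated dose is
not over-weighted. Fits with fewer than two distinct doses, or with a
non-positive slope, are errors rather than silent bad numbers.

`combination_index()` evaluates the two-term (mutually exclusive)
combination index on a constant-ratio design:

$$ CI(f_a) = \frac{D_1}{D_{x1}(f_a)} + \frac{D_2}{D_{x2}(f_a)} $$

where $D_1, D_2$ are the component doses actually delivered at each
combination point and $D_{x1}, D_{x2}$ are the single-agent doses
producing the same effect under each fitted curve. CI is reported at the
fitted effect of every experimental combination dose and at ED50, ED75
and ED90. CI is dimensionless and invariant under a consistent
rescaling of dose units; a sham self-combination yields CI = 1 at every
effect level, which the tests assert.

```{r}
g <- gen_dose_response(seed = 1, model = "potency_synergy", alpha = 2)
combination_index(g$design)$summary_CI
```

## CDI and excess over Bliss

`normalize_viability()` divides raw well signals by the mean vehicle
signal. `cdi()` computes $\mathrm{CDI} = \overline{AB}/(\bar A \cdot
\bar B)$ on surviving fractions; values below 1 indicate synergy. The
p-value compares the $AB$ replicates against the replicate-paired
products $A_i B_i$ with a Welch two-sample t-test. Welch rather than an
equal-variance test is deliberate: the product arm has roughly twice the
variance of the $AB$ arm (it multiplies two noisy measurements), so the
pooled-variance statistic is anticonservative — in simulation its
type-I error under the independence null is ~0.075 at triplicates,
whereas Welch holds ~0.05. For the same reason the plate generator
defaults to `n_vehicle = 2 * n_rep`: the vehicle mean normalizes every
arm, so extra replication of the anchor reduces the correlated error it
injects into all groups.

`excess_over_bliss()` takes an inhibition matrix whose first row and
column are the zero-dose margins, forms the Bliss expectation
$E_A + E_B - E_A E_B$ from those margins, and reports per-cell
`observed - expected` plus `mean_score` (100 × mean excess over all
nonzero-dose cells). Inputs outside $[0, 1]$ are clipped and counted.

## Synergy-gene calling

`call_synergy_genes()` implements the ratio rule on condition means:
with $A$, $B$, $C$ the single-drug and combination changes versus
vehicle, a gene is synergistic when $C/(A+B) \ge 1.25$ (inclusive), "up"
when the combination mean exceeds vehicle and "down" when below; genes
with $|A+B|$ below `eps = 1e-9` are "undefined". The rule is invariant
under joint positive rescaling of a gene's means, so expression units do
not matter. An optional `significance_mask` restricts calls;
`welch_significance_mask()` (per-gene Welch tests versus vehicle,
Benjamini–Hochberg at `alpha = 0.005`) is a simple stand-in for a full
differential-expression pipeline. `intersect_gene_set()` scores overlap
of calls with a curated set by the hypergeometric upper tail over the
classified universe; `p53_dependence()` partitions one run's calls by
whether they survive in a paired knockdown run.

## mRNA stability from delta-Ct

`relative_abundance()` converts Ct values to abundances relative to
time 0 as $\mathrm{efficiency}^{Ct_0 - Ct}$, with `efficiency = 2`
(perfect doubling per cycle) as default. `fit_decay()` fits
$\ln(\mathrm{abundance})$ against time with a free intercept; the decay
rate is $k = -$slope and `half_life` $= \ln 2 / k$. A non-positive $k$
yields an infinite half-life with a warning rather than a negative one.
`compare_stability()` flags any ratio involving an infinite half-life
as undefined. At least three time points are required; replicate Ct
values at the same time are averaged before the transform.

## Peaks and intervals

All coordinates are 0-based half-open (BED convention), converted to
1-based closed form only at the GenomicRanges boundary.
`consensus_peaks()` merges each replicate internally (so one replicate
contributes at most 1 to any base), sums base-level support and slices
maximal runs with support at least `min_support`; `min_support = 1` is
the union and `min_support = n` the intersection. `annotate_peaks()`
labels a peak "promoter" if it overlaps a TSS ± `promoter_window`
(default 2000 bp) window, else "genic" on gene-body overlap, else
"intergenic"; promoter takes precedence. `gene_binding_matrix()` calls
a gene bound when any consensus peak overlaps its body extended by
`window` (default 5000 bp) on both sides. All four operations are
verified against a brute-force per-base oracle in the test suite.

## Synthetic-data generators and their scope

Each generator derives a private stream from the root seed via
`derive_seed(seed, label)`, so adding a generator to a workflow never
perturbs another's draws. Ground truth is always returned alongside the
data. Noise models: lognormal multiplicative noise on survival
fractions, raw plate signals and expression values; additive normal
noise on Ct (cycles); uniform boundary jitter and Bernoulli dropout on
peaks. Loewe-additive combination responses are solved by bisection of
the dose-equivalence relation to tolerance 1e-10, so "additive" truths
give CI = 1 to well below test tolerances, and `potency_synergy` with
multiplier $\alpha$ gives CI $= 1/\alpha$ exactly.

`gen_expression_matrix()` deliberately emulates the *strongly
drug-responsive* part of a transcriptome (default 6000 genes, induced
genes 4–7× per drug, repressed genes 46–50% per drug; planted synergy
ratios ≥ 1.4; null genes exactly additive). This scope is a modeling
choice, not a limitation of the caller alone: the ratio $C/(A+B)$ has a
noise-dominated denominator for weakly responding genes, so *no* caller
based on this statistic is reliable there, and the study design this
package mirrors applies the rule to significantly changed genes only.
The calibration was performed once at design time and frozen.

Typical problem sizes run in seconds: 6-point dose curves, 6×6 dose
grids, $10^3$–$10^4$ gene tables with 3 replicates, 1 Mb toy genomes
with hundreds of peaks.

## Numerical choices, collected

- fraction-affected clipping bound: 1e-4 (reported per point)
- Loewe bisection tolerance: 1e-10 on $f_a$
- synergy-rule denominator guard `eps`: 1e-9 (→ "undefined")
- tied doses: averaged on the log-odds scale before fitting
- hypergeometric tail: `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`
- decay fit: free intercept (no forcing through abundance 1 at t = 0),
  so a noisy anchor point does not bias $k$
- promoter interval: TSS ± window, clamped at position 0
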