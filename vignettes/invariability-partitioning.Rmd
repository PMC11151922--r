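---
title: "Methods: partitioning temporal invariability in plant–pollinator metacommunities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning temporal invariability in plant–pollinator metacommunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollistab)
```

## The model

`pollistab` treats a surveyed metacommunity variable as a dense tensor of
non-negative values indexed by *unit* (a plant species, a pollinator
species, or a plant–pollinator pair), *patch* (a site) and *time* (a year).
Temporal invariability is the inverse coefficient of variation, `1/CV`,
`CV = sd/mean`, of a time series at some level of aggregation. The
partition expresses the CV of the region-wide aggregate exactly as a
product of lower-level CVs and synchrony ratios. All four weighted CVs
share one denominator, the temporal mean `mu` of the region-wide total
series; their numerators are sums of temporal standard deviations of
population series (`CV_S,L`), of patch-total series (`CV_C,L`), of
unit-regional series (`CV_S,R`), or the single SD of the grand total
(`CV_C,R`). Each synchrony index is then a ratio of two of these CVs, and
subadditivity of the SD of a sum (`sd(x + y) <= sd(x) + sd(y)`) confines
every index to `[0, 1]`. Two consequences the package leans on:

* the decomposition is exact, not approximate — `var_partition()` asserts
  the multiplicative identities and path consistency, and the test suite
  verifies them to `1e-10` against an independent brute-force
  implementation on randomized inputs;
* invariability is structurally non-decreasing from populations to
  communities to the region. `level_ordering_check()` therefore reports
  this ordering as a *consistency assertion* about the arithmetic; the
  biology lives in *how far below 1* the synchrony indices fall, not in the
  ordering itself.

The same machinery is applied to four system variables per study: floral
availability (units = plant species), pollinator visitation rates
(units = pollinator species, visits summed over plants), interaction
frequencies (units = plant–pollinator pairs) and fruit set (units = plant
species, values in `[0, 1]`). The visitation and interaction tensors are
built from the same records, and `run_study()` asserts that collapsing the
pair tensor over plants reproduces the pollinator tensor.

## Conventions that were genuinely open, and how we fixed them

**CV definition.** We use `CV = sd/mean` throughout. The variance-over-
squared-mean quantity sometimes quoted in this literature is `CV^2`; only
the `sd/mean` form satisfies the multiplicative identities above, so the
package commits to it.

**Synchrony scale.** Synchrony is defined as the *ratio of CVs*
(equivalently, a ratio of an aggregate SD to a sum of SDs — the
"square-root" scale). A variance-scale alternative (the square of ours)
circulates in the literature; it is exposed via
`var_partition(synchrony_scale = "variance")` for comparison, but the
identities, the `[0, 1]` bound interpretation, and all defaults use the CV
ratio, because that is the scale on which `CV_C,R = CV_C,L * Ψ` holds.

**Sample SD.** Standard deviations use the `n - 1` denominator, matching
the reference implementations of this framework. With two years of data —
the design the generator emulates — `sd = |x1 - x2|/sqrt(2)`.

**Taylor's law convention.** We estimate the scaling exponent `b` by OLS of
`log10(sd)` on `log10(mean)` (default `sd_vs_mean`). Under this convention
`b = 0.5` is exactly the "variance proportional to mean" (Poisson-like)
regime, `b = 1` constant CV, `b = 0` constant SD, and negative `b` —
variance decreasing with abundance — is permitted and simply reported. The
literal `Var = a * mean^b` regression is available as `var_vs_mean` (its
slope is twice ours); every fit records its convention so the two
parameterizations cannot be silently mixed.

**Which units enter the regional Taylor regression.** There is no single
established choice; `taylor_units(level = "region")` pools the population
and community pairs, and the population/community levels are available
separately. Series with zero mean or zero SD carry no information on a
log–log scale and are excluded with a reported count.

## Aggregation rules for survey data

* Duplicate keys in a survey CSV are **summed**, not rejected — field
  sheets legitimately split one observation across rows; the merge count is
  reported.
* Subplots and within-year sampling rounds are aggregated to one value per
  (unit, site, year). Rounds are summed by default (`annualize = "sum"`,
  the season total); `"mean"` divides by the global round universe, which
  only rescales every cell by the same constant and therefore leaves all
  CVs and synchronies unchanged when all site-years share the round
  design.
* A species or pair absent from a site-year is a **true zero** for that
  year and is zero-filled, with the unit universe global across sites so
  regional sums are well defined. This matters: zero-filling contributes to
  temporal SDs, as it should for count-like abundances.
* Fruit set is the exception: an unmeasured plant-site-year is **missing,
  not zero** (`NA`), and the partition for fruit set runs on the
  complete-case unit subset with a warning. A pooled estimate
  (total fruits / total flowers marked, flower-weighted) is the default;
  an unweighted mean of individual proportions is available.
* Visitation is left as raw visit totals per site-year by default — in the
  emulated design census effort is constant (three one-hour censuses in
  each of eight rounds), so totals are comparable across site-years. A
  per-flower rate (site-year visits divided by the site-year community
  flower total) is available via
  `study_config(visit_normalization = "per_flower")`.

## Numerical choices and degenerate inputs

* An all-zero tensor is an error ("degenerate metacommunity"), as is a
  non-positive regional mean or a single year of data.
* A `0/0` synchrony ratio (every component series constant) is reported as
  **1 with a degeneracy flag** rather than an error, so batch runs over
  many variables survive a degenerate one. A zero denominator with a
  non-zero numerator cannot occur (subadditivity).
* A CV of zero maps to invariability `+Inf`, again flagged rather than
  errored.
* Taylor fits require at least three usable pairs and at least two distinct
  means; `R^2` is computed directly from residual and total sums of squares
  (clamped to `[0, 1]`), so exact analytic fits do not emit spurious
  warnings.

## What the generator emulates

`synth_config()` encodes a two-trophic survey campaign patterned on a
Mediterranean shrubland design: `M = 5` sites surveyed over `R = 8`
biweekly rounds per flowering season for `T = 2` years, `S = 8` focal plant
species (the number on which fruit set is typically scored in such
campaigns), `A = 12` pollinator species, and `n_individuals = 7` marked
individuals per plant-site-year (roughly 540 individuals over two years,
the order of magnitude such a campaign yields). Where the emulated design
is silent we chose once: `rho_species = rho_spatial = 0.3` (moderate,
partially compensatory dynamics), species mean annual flower abundances
log-uniform on `mu_range = c(5, 100)`, `taylor_b = 0.5` with `cv_ref =
0.35` (a CV of 35% at the geometric-mean abundance — mid-range for annual
floral production), `visit_rate = 0.05` visits per flower per round per
pollinator at uniform preference (about 0.5 annual visits per flower
summed over a dozen pollinators), `halfsat = 0.5` annual visits per flower
and `fruitset_max = 0.8` (fruit set responds steeply at low visitation and
saturates below 1, as in self-incompatible shrubs), logit-scale individual
noise `noise_sd = 0.3`.

The causal chain mirrors the two-trophic adaptation of the framework:
correlated flower abundances → visits driven by floral availability,
Dirichlet-distributed pollinator preferences
(`preference_concentration`) and pollinator activity fluctuations →
fruit set as a saturating (Michaelis–Menten) function of annual visits per
flower, binomial at the individual level. The saturating form is a
modelling choice of the generator, not an estimated relationship.

**Fluctuation structure.** Annual log-abundance fluctuations follow a
unit-variance Gaussian field with a separable exchangeable correlation
structure (shared global, site, and species components), so that the
between-species correlation within a site is `rho_species` and the
between-site correlation of one species is `rho_spatial`. Log-normal
moments are matched so the raw-scale mean is `mu_s` and the raw-scale SD is
`c * mu_s^taylor_b` *before* rounding to counts; `c` is anchored by
`cv_ref`. Counts are obtained by rounding, which controls `taylor_b`
essentially exactly; a `count_model = "poisson"` mode instead draws i.i.d.
Poisson counts with time-constant rates, making temporal variance equal
temporal mean by construction (scaling exponent 0.5) — the stochastic
anchor used by the acceptance script.

**Ground truth.** `expected_synchrony()` returns the closed-form large-`T`
species synchrony `sqrt((1 + (S-1) rho_species)/S)` (equal-SD species) and
its spatial analogue `sqrt((1 + (M-1) rho_spatial)/M)`. These are exact for
the underlying Gaussian field and approximate after exponentiation and
rounding — the log-normal transform shrinks Pearson correlations slightly —
so recovery tests use an absolute tolerance of 0.05.

**What the generator does *not* emulate.** No mechanistic population
dynamics (no density dependence or Lotka–Volterra coupling), no phenology
within the season (rounds are a multinomial scatter of the annual total),
no spatial kernels beyond exchangeable correlation, no observation error on
counts, and sessile plants fixed to one subplot. Passing tests therefore
show that the *statistics* recover known structure from data of the right
shape and scale; they do not validate any ecological claim about real
communities.

## Validation design and problem sizes

The test suite validates the pipeline at sizes chosen to make Monte-Carlo
error small relative to the tolerances while keeping the default run fast:

* partition correctness: 200 random tensors (up to 4 units × 3 patches × 6
  years) against an independent loop-based oracle, to `1e-10`, plus exact
  frozen values for a 2 × 2 × 3 worked example;
* synchrony recovery: `S ∈ {2, 5, 10}` equal-abundance species,
  `rho_species ∈ {0, 0.3, 0.8}`, one site, `T = 200` years, 20 seeds per
  cell, mean estimate within 0.05 of the closed form;
* Taylor recovery: Poisson mode, 30 population units, `T = 50`, mean
  fitted `b` over 10 seeds within 0.1 of 0.5;
* plus schema, determinism, degeneracy and ordering checks throughout.

## Known limitations

* With two years — the design the generator emulates — every temporal SD
  rests on two points; the partition is exact arithmetic regardless, but
  sampling variance of each component is large, and no confidence
  intervals are provided (a block bootstrap is meaningless at `T = 2`).
* The CV-based framework assumes roughly symmetric fluctuations and is
  sensitive to outliers and to mean–variance coupling; the per-level
  Taylor fits are provided precisely to inspect that coupling.
* Fruit set is a bounded proportion; its SDs and CVs are computed on the
  raw proportion scale, and the complete-case unit subset may bias the
  fruit-set partition when missingness is not random.
* The partition quantifies pattern (how much synchrony, at which level); it
  does not identify mechanism, and the generator's path structure is a
  forward simulation, not an estimated causal model.
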