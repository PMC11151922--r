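# pollistab

Hierarchical partitioning of the temporal invariability of plant–pollinator
metacommunity variables across organizational levels, with Taylor's
power-law mean–variance scaling and a synthetic two-trophic metacommunity
generator.

## The problem

Pollination-dependent ecosystem functioning (fruit set) emerges from
interactions between two trophic levels. How stable that functioning is
depends on where you look: single populations fluctuate strongly from year
to year, yet communities and whole regions are often far steadier, because
species within a community and communities across a region fluctuate out of
step with one another (the insurance hypothesis). `pollistab` quantifies
this for four system variables measured by standard field surveys — floral
availability, pollinator visitation rates, plant–pollinator interaction
frequencies and fruit set — by decomposing temporal variability across the
population → community → region hierarchy.

## The statistics

Stability is measured as temporal invariability, the inverse coefficient of
variation `1/CV`, with `CV = sd/mean`. For a unit × site × year tensor of a
variable, with `mu` the temporal mean of the region-wide total, the four
weighted CVs are

```
CV_S,L = sum over populations of sd(unit-site series)   / mu
CV_C,L = sum over sites of sd(site total series)        / mu
CV_S,R = sum over units of sd(unit regional series)     / mu
CV_C,R = sd(region-wide total series)                   / mu
```

("unit" is a plant species, pollinator species, or plant–pollinator pair
depending on the variable). Synchrony indices are ratios of CVs, so the
decomposition is exact and multiplicative:

```
CV_C,R = CV_C,L · Ψ_C,L→R          (spatial synchrony)
CV_C,L = CV_S,L · Ψ_S→C,L          (species synchrony)
```

and likewise along the species route (`Ψ_S,L→R`, `Ψ_S→C,R`), with both
routes meeting at `CV_C,R / CV_S,L`. Subadditivity of standard deviations
guarantees every `Ψ ∈ [0, 1]`, so invariability can only increase (or stay
flat) with organizational level; values of `Ψ` well below 1 indicate
compensatory, stabilizing dynamics.

Taylor's power law is fitted per hierarchical level by OLS on the log–log
mean–SD relationship; under this convention the slope `b = 0.5` corresponds
to variance proportional to the mean (Poisson-like), `b = 1` to constant CV.

## Worked example

```r
library(pollistab)

dat <- simulate_metacommunity(synth_config(seed = 42))  # 8 plants, 12 pollinators, 5 sites, 2 years
res <- run_study(dat$flowers, dat$visits, dat$fruitset)
res
#> # study_result: 4 variable(s) partitioned (flower_availability, visitation_rate, interaction_frequency, fruit_set)
#> # invariability by level:
#> # A tibble: 4 × 5
#>   variable              inv_population inv_community inv_region ordering_holds
#>   <chr>                          <dbl>         <dbl>      <dbl> <lgl>
#> 1 flower_availability             6.41         12.1        62.8 TRUE
#> 2 visitation_rate                 2.40          6.13       27.0 TRUE
#> 3 interaction_frequency           1.68          6.13       27.0 TRUE
#> 4 fruit_set                       5.16         11.2       101.  TRUE
```

Invariability rises roughly an order of magnitude from populations to the
region for every variable — the qualitative signature of asynchronous
dynamics. The synchrony indices behind it:

```r
glance(res)[, c("variable", "phi_s2c_l", "phi_c_l2r")]
#> # A tibble: 4 × 3
#>   variable              phi_s2c_l phi_c_l2r
#> 1 flower_availability       0.531     0.192
#> 2 visitation_rate           0.391     0.227
#> 3 interaction_frequency     0.274     0.227
#> 4 fruit_set                 0.461     0.110
```

Species synchrony around 0.3–0.5 and spatial synchrony around 0.1–0.2 mean
populations within a community, and communities across the region, buffer
one another substantially. A Taylor fit on the interaction-frequency
populations:

```r
tn <- build_tensor(dat$visits, "interaction_frequency")
taylor_fit(taylor_units(tn, "population"), level = "population")
#> # taylor_fit (sd_vs_mean, level = population): b = 0.5260, intercept = 0.0113, R^2 = 0.493, n = 312
```

`b ≈ 0.5`: variance scales linearly with mean interaction frequency.
`autoplot(res)`, `plot_synchrony(res)` and `autoplot(fit)` draw the
corresponding figures; `tidy()`/`glance()` return everything as tibbles and
`write_study_summary()` exports the tidy long table.

Field data enter through `read_survey_table(path, kind)` with the CSV
schemas `year,round,site,subplot,plant,count` (flowers),
`...,plant,pollinator,visits` (visits) and
`year,site,plant,individual,flowers_marked,fruits` (fruit set).

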