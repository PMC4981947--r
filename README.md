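# bloomkit

Analysis toolkit for **non-seasonal zooplankton blooms in shallow tropical
soda lakes** — for limnologists and quantitative ecologists working with
weekly plankton monitoring data.

Rotifer populations in East-African soda lakes (dominated by *Brachionus
dimidiatus*, *B. plicatilis* and *Hexarthra jenkinae*) erupt into blooms of
up to 10⁵–10⁶ individuals L⁻¹ with no seasonal pattern and no coupling to
food conditions. `bloomkit` implements the full chain of methods used to
dissect such blooms and to test the hypothesis that they are fed by
resting-egg hatching from the sediment egg bank, triggered by sediment
resuspension:

* **Egg-ratio demography** — growth rate *r* = (ln N₂ − ln N₁)/(t₂ − t₁),
  birth rate *b* = ln(1 + N_E /(D_E · N♀)) with temperature-dependent egg
  development time D_E(T), and death rate *d* = *b* − *r*; negative *d*
  flags external recruitment.
* **Population projection** — N(t+Δ) = N(t)·exp(Δ(b − d)) under scenario
  death rates {0, 0.11, 0.43} d⁻¹, with Poisson-bootstrap 95% envelopes, and
  the conservative external-recruitment estimate
  `observed − upper95`, floored at zero.
* **Bloom detection** — onset rule (biomass jump > factor *and* above an
  absolute or lake-specific CI threshold), mixed-effect logistic
  bloom-probability models (lake random intercept, adaptive quadrature),
  all-subsets AIC selection, paired pre-bloom contrasts, bloom frequency.
* **Lagged variance partitioning** — (partial) redundancy analysis of the
  species matrix on intrinsic-growth vs hatching-proxy (particulate matter)
  predictor sets, unique/shared/residual fractions with Ezekiel adjustment,
  reduced-model permutation tests, and a 0–7-week lag scan at constant *n*
  with Bonferroni correction.
* **Changepoint detection** — least-squares mean-shift segmentation by
  dynamic programming with penalized-contrast selection of the number of
  segments.
* **Energy budget** — export of aquatic primary production to land via
  flamingo grazing: `export = ingested × (1 − returned)`.
* **Synthetic multi-lake generator** — weekly series with
  resuspension-triggered hatch pulses at a known stimulus→hatch lag,
  resource-driven egg ratios, injected phytoplankton breakpoints, and a
  ground-truth ledger, so every estimator above is testable end to end.

## Worked example

```r
library(bloomkit)

cfg <- sim_config(n_lakes = 1, seed = 42)
sim <- simulate_lakes(cfg)
sim
#> Synthetic soda-lake dataset: 1 lakes x 35 weeks (35 samples)
#> Species: B_dimidiatus, B_plicatilis, H_jenkinae
#> Ground truth: 15 hatch pulses, stimulus-to-hatch lag 3 wk

detect_bloom_onsets(sim$lakes[[1]])
#> Bloom onsets: 3 of 34 usable samples (rule: factor 3.0, mode 'either')
#>   lake_id index biomass class
#> 1       1     8   10.67  8-20
#> 2       1    17    6.39   4-8
#> 3       1    27    6.05   4-8
```

Three onsets were flagged: weeks where total rotifer biomass more than
tripled and exceeded the bloom threshold (the `class` column is the
magnitude band in g DM m⁻³). Was the first of them fed by pelagic
reproduction, or by hatching from the sediment? Project the population from
the pre-bloom week using only the egg-derived birth rates and the harshest
mortality scenario (d = 0.43 d⁻¹, the field mean), and compare with what was
observed:

```r
est <- estimate_bloom_recruitment(sim, reps = 1000, seed = 42)
est$estimate
#> External-recruitment estimate (conservative, upper-95% based)
#>   observed 8.21e+04 ind/L, modelled upper bound 1.38e+03 ind/L
#>   external 8.07e+04 ind/L = 98.3% of the observed population
```

Pelagic reproduction can account for at most ~1.4 × 10³ ind/L by the onset
week; the remaining 98% of the observed bloom must have hatched from the
egg bank — and the generator's ledger confirms it injected 8.2 × 10⁴
hatchlings that week (true external fraction 0.999). The same machinery
applied to the field numbers of the original bloom (observed 1.65 × 10⁵
ind/L vs a modelled upper bound of 5.5 × 10⁴) attributes two thirds of the
observed population to resting-egg recruitment:

```r
external_recruitment(observed = 1.65e5, ensemble = 5.5e4)
#> External-recruitment estimate (conservative, upper-95% based)
#>   observed 1.65e+05 ind/L, modelled upper bound 5.5e+04 ind/L
#>   external 1.1e+05 ind/L = 66.7% of the observed population
```

Rotifer grazing restructures the phytoplankton; the injected collapse of
small algae is localized exactly:

```r
detect_breakpoints(sim$lakes[[1]], "small_algae")
#> Penalized-contrast segmentation of `small_algae`: 2 segment(s)
#>   breakpoints after indices: 11
#>   segment means: 7.995, 1.536

energy_budget(0.60, 1/3)
#> Energy budget: 60% of daily primary production ingested, 33% of that
#> returned -> 40% removed from the aquatic food web
```

The methods vignette (`vignettes/bloom-dynamics.Rmd`) documents the models,
their assumptions, the generator's design and its limitations.

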