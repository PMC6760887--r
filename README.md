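# riskspace

Prey space use under spatial and temporal variation in predation risk.

`riskspace` is an R implementation of a before-after-control-impact (BACI)
radio-telemetry analysis for hunted bird populations — the motivating
system is Ring-necked Pheasants on grassland sites that are either open
("high-risk") or closed ("low-risk") to public hunting. Because hunters
may harvest only males, females on hunted sites experience *perceived*
predation risk without depredation, letting the analysis separate
behavioural responses to risk from the direct demographic effect of
harvest. The package is aimed at movement and behavioural ecologists who
want the full chain — triangulation, home ranges, risk metrics, mixed
models, vegetation PERMANOVA, survival — as tested, reusable functions
rather than a one-off script.

## What it computes

* **Triangulation** — maximum-likelihood (Lenth-type, von Mises error)
  positions from azimuth sets, with 95% error ellipses
  `A = π √det(Σ) χ²₂,₀.₉₅` and the field-protocol precision filter
  (≤ 2000 m² daytime, ≤ 1000 m² roost fixes).
* **Hunting pressure** — mean hunters per camera photo, per site, per day,
  with the season calendar: pre (1–25 Oct), early (27 Oct – 23 Nov), late
  (24 Nov – 15 Dec).
* **Kernel home ranges** — fixed-kernel utilization distributions with the
  reference bandwidth `h = 0.5 (sx + sy) n^(-1/6)`; 95% and 50% isopleth
  areas and core centers, per individual × season (≥ 10 fixes), plus
  center shifts between seasons.
* **Moving windows** — 11-relocation sliding home ranges advanced one fix
  at a time, each attributed the hunting pressure of the site its 95%
  range overlaps most (low-risk mean when offsite), and steps between
  successive core centers carrying the previous window's pressure.
* **Mixed-model inference** — Gaussian LMMs (REML via `lme4`) with
  5000-draw flat-prior posterior simulation, 95% credible intervals,
  CI-exclusion significance and posterior group-mean contrasts.
* **Roost vegetation** — PERMANOVA (`vegan::adonis2`, sequential SS) under
  a one-roost-per-individual-per-season subsample bootstrap (1000
  iterations; median F with 2.5/97.5% bounds; significant if median
  p < 0.05).
* **Mortality** — product-limit surviving-proportion curves by sex × risk
  group and first-ten-day mortality tables.
* **Synthetic data** — a ground-truth generator (mean-reverting movement,
  Poisson camera counts, pressure-driven male harvest, vegetation with
  group and date structure) so the whole pipeline is testable end to end.

## Worked example

```r
library(riskspace)

truth <- simulation_truth(n_per_sex_group = 10, seed = 42)
ds <- simulate_dataset(truth)
ds
#> Synthetic study: 10 sites, 40 individuals, 1836 relocations, 500 camera-days

pressure <- daily_pressure(ds$camera_days, ds$sites)
aggregate(pressure ~ group + season, pressure, mean)
#>   group season pressure
#> 1  high  early  0.00571
#> 2   low  early  0.00048
#> 3  high   late  0.00114
#> 4   low   late  0.00083
```

Early-season pressure on hunted sites is an order of magnitude above the
low-risk sites and collapses toward parity late in the season. The risk
mixed model (intercept = high-risk/early) makes that quantitative:

```r
fit_risk_model(pressure, seed = 1)$summary
#>                  term estimate    mean    q2.5   q97.5 significant
#> 1         (Intercept)   0.0057  0.0057  0.0049  0.0065        TRUE
#> 2            grouplow  -0.0052 -0.0052 -0.0063 -0.0041        TRUE
#> 3          seasonlate  -0.0046 -0.0046 -0.0056 -0.0035        TRUE
#> 4 grouplow:seasonlate   0.0049  0.0049  0.0034  0.0065        TRUE
```

Female seasonal home ranges show the risk response: on high-risk sites the
mean 95% range roughly doubles in the early season and reverts late
(hectares):

```r
hr <- seasonal_home_ranges(ds$relocations)
aggregate(area95_ha ~ group + season, hr[hr$sex == "F", ], mean)
#>   group season area95_ha
#> 1  high    pre      85.4
#> 2   low    pre      68.6
#> 3  high  early     167.0
#> 4   low  early      86.8
#> 5  high   late      73.1
#> 6   low   late      63.3
```

while ten-day mortality concentrates in the only vulnerable cell,
high-risk males:

```r
early_mortality_table(ds$fates)
#>   sex group n_onset mortality_pct
#> 1   F  high      10           0.0
#> 2   F   low      10          10.0
#> 3   M  high       9          23.8
#> 4   M   low       9           0.0
```

The whole chain — simulate (or read) a dataset, triangulate, filter,
pressure, seasonal + moving-window home ranges, the six-model mixed-model
suite, three bootstrapped PERMANOVAs and the survival summaries — runs as
one call (or via `scripts/run_pipeline.R` from a shell):

```r
run_pipeline(run_config(seed = 1), "simulate",
             data_dir = "data", out_dir = "results")
```

writing `pressure.csv`, `home_ranges.csv`, `shifts.csv`, `windows.csv`,
`window_steps.csv`, `model_results.csv`, `permanova_results.csv`,
`survival_curves.csv`, `mortality_table.csv` and a run manifest.

## Scope notes

Methodological choices, defaults, numerical tolerances and known
limitations (notably the anti-conservatism of significance flags in
overlapping-window models) are documented in
`vignettes/space-use-under-risk.Rmd`.
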