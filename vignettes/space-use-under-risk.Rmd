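---
title: "Methods: prey space use under spatial and temporal predation risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prey space use under spatial and temporal predation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`riskspace` implements a before-after-control-impact (BACI) analysis of how
recreational hunting — a predator that may legally take only males — shapes
the space use of a radio-marked galliform population. Sites fall in two risk
groups (open vs closed to public hunting); the field season splits into a
pre-season control period (1–25 October), an early hunting season with
concentrated pressure (27 October – 23 November) and a late season with
relaxed pressure (24 November – 15 December). Because females are never
harvested, any change in female space use on hunted sites isolates
*perceived* predation risk from depredation itself. The pipeline takes raw
bearing sets through maximum-likelihood triangulation, estimates fixed-kernel
utilization-distribution (UD) home ranges at two temporal scales, fits
Gaussian linear mixed models with posterior-simulation credible intervals,
tests roost-site vegetation with a subsample-bootstrapped PERMANOVA, and
summarizes harvest mortality with product-limit surviving proportions.

## Triangulation

A transmitter location is estimated from two or more azimuths by maximizing
a von Mises bearing-error likelihood (the classical Lenth estimator family):
with station positions $S_i$ and observed azimuths $\theta_i$ (degrees
clockwise from north), the estimate maximizes
$\kappa \sum_i \cos(\theta_i - \mu_i(z))$ where $\mu_i(z)$ is the azimuth
from $S_i$ to the candidate point $z$. We initialize at the least-squares
intersection of the bearing lines and refine with damped Newton steps
(tolerance $10^{-8}$ m on the step, at most 100 iterations; non-convergence
is flagged and the fix excluded). The covariance of the estimate is the
inverse observed information and the error ellipse is the 95% confidence
ellipse, $A = \pi\sqrt{\det\Sigma}\,\chi^2_{2,0.95}$; this convention makes a
2000 m² ellipse correspond to roughly a 25 m radius, matching the field
protocol's quality rule. The assumed bearing SD is not recoverable from the
study's closed-source field software, so it is exposed as a parameter
(default 3°); it scales ellipse areas but not point estimates. Daytime
(foraging, loafing) fixes are retained at ellipse areas up to 2000 m²;
roosting fixes only up to 1000 m², because roosts must be physically
re-found for vegetation sampling.

## Kernel home ranges

UDs are bivariate Gaussian fixed-kernel densities with the ad-hoc reference
bandwidth $h = 0.5\,(s_x + s_y)\,n^{-1/6}$, the convention of the classical
home-range estimator family this analysis follows (no cross-validation; the
small per-estimate sample sizes make LSCV unstable). The density is
evaluated exactly on a square-celled grid via the kernel's separability,
with the extent padded by $3h$ so that truncation loss is below 1%, then
renormalized to integrate to exactly 1. A $p$-isopleth is the smallest set
of cells holding fraction $p$ of the mass (cells accumulated by decreasing
density); the 95% isopleth is the home range, the 50% isopleth the core
area, and the core's density-weighted centroid is the "home range center"
(a density mode is available as an option; the centroid is the default
because it is stable under multimodality). Default grids are 200 cells
along the longer side for seasonal estimates; grid-refinement tests show
95% areas change by under 2% when the cell size is halved.

Seasonal estimates require at least 10 relocations per individual-season;
individuals are eligible per season independently. Center shifts are
Euclidean distances from the pre-season core center to the early- and
late-season centers, so individuals missing either member of a pair drop
out of that contrast — mirroring the paired-sample reduction inherent in a
BACI location analysis.

## Moving windows

The sliding-window estimator treats space use and risk as continuous: each
window is the focal relocation plus its five predecessors and five
successors (11 fixes), advanced one relocation at a time, so $n$ fixes
yield $\max(0, n-10)$ windows. Each window gets its own reference bandwidth
(recomputed per window rather than fixed per individual — the estimator
should track local behaviour; a switch retains the alternative), a
window length (days from first to last member fix, a covariate in all
window models), and a hunting pressure: the mean hunters per photo per site
per day of the site whose polygon most overlaps the window's 95% region
over the window's date range. Overlap is measured as the count of
95%-region cell centers inside each site polygon, with ties broken by site
id for determinism. Windows intersecting no site take the mean over
low-risk sites for the same dates (a conservative offsite rule: most
surrounding land was not publicly huntable). Days before the season opening
carry zero pressure by definition — cameras only operate during the
season, and no legal hunting exists before it — while in-season days
missing from the camera record are dropped from the mean rather than
imputed as zero. Window grids default to 60 cells per side: with 11-point
windows the discretization error on areas is within the same 2% envelope
at a fraction of the cost (the seasonal default of 200 would be ~10×
slower for no measurable gain at this sample size).

Steps between successive windows are distances between their 50% centers,
attributed the *previous* window's pressure (the risk the bird is moving
away from); the previous window's median date and window length are used as
that step's covariates for the same reason.

## Mixed models and posterior simulation

All inference models are Gaussian linear mixed models fitted by REML
(`lme4`), with natural-log responses where areas or distances are modelled
(intercepts near $\ln(100\,\mathrm{ha}) \approx 4.6$ confirm the scale).
The suite comprises: hunting pressure ~ risk group × season(early, late)
with a site intercept (reference cell high-risk/early); per-sex seasonal
log area and log shift-distance ~ risk × season (+ year when more than one
cohort is present) with site and individual intercepts (reference
low-risk/pre); and the moving-window log area and log step-distance ~ log
pressure + sex + median season day + window length (+ year), site and
individual intercepts (reference female). Hunting pressure enters on the
log scale; because pre-season pressure is exactly zero we use
$\log(\text{pressure} + 0.001)$, the offset being one hunter per thousand
photos — below any observable nonzero value; it is exposed as a
configuration parameter.

Uncertainty is summarized by posterior simulation under flat priors: each
of 5000 draws takes a residual variance from its scaled inverse-$\chi^2$
conditional and a coefficient vector from a multivariate normal centred at
the REML estimates with covariance rescaled by that draw. The 2.5% and
97.5% quantiles of the draws form 95% credible intervals; a term is
"significant" when its interval excludes zero, and group-specific posterior
means (and their differences) are linear functions of the same draws. At
$10^6$ draws these intervals agree with Wald intervals to under 1% of the
interval width, and the CI-exclusion rule holds its nominal 5%
false-positive rate on null simulations of the seasonal models.

## Roost-site PERMANOVA

Six vegetation measures (warm- and cool-season grass, bare ground and
litter cover in percent; litter depth in cm; a visual-obstruction score)
are compared with a permutational MANOVA on a distance matrix, testing
risk group, sex, their interaction and date (entered in that order,
sequential sums of squares, free row permutation, 999 permutations by
default, $p$ never exactly zero by the $+1$ convention). The variables mix
units, so the default distance is Euclidean on column-standardized values;
Bray–Curtis on raw non-negative values is available. In the single-variable
Euclidean case the pseudo-$F$ collapses exactly to the classical one-way
ANOVA $F$, which the tests exploit as an independent oracle. Date enters
as a continuous day-of-study covariate.

Because individuals contribute unequal numbers of roosts, each bootstrap
iteration draws one plot per individual per season, runs the PERMANOVA,
and after 1000 iterations reports each term's median $F$ with 2.5%/97.5%
bounds and median $p$; a term is accepted as significant when the median
$p < 0.05$. Three datasets are analysed: pre-season roosts, within-season
roosts, and the paired non-use plots (established 35 m from each roost).

## Mortality summaries

Surviving proportions by sex × risk group are product-limit estimates
anchored at the season opening; collar losses are right-censored (an
exclusion mode is provided since the field protocol does not dictate the
convention), and with no censoring the estimator reduces exactly to the
naive alive-count ratio. The headline summary is percent mortality over
the first ten season days per cell, which under the default synthetic
truth concentrates almost entirely in high-risk males.

## The synthetic study and what it does (not) emulate

The generator is first-class, tested code: it emulates ten rectangular
sites of 29–155 ha in two risk groups, 3–7 tracking days per week from
1 October to 15 December, one location type per tracking event, Poisson
hunters per photo at 120 photos/site/day (rates 0.006 early-high, 0.0014
late-high, 0.0007 low — the early-high regime an order of magnitude above
low-risk), and male-only harvest with per-day probability proportional to
that day's realized site pressure plus a 0.003/day natural hazard (about
30% ten-day mortality for high-risk males at the default hazard
coefficient of 6). Movement is a daily bivariate mean-reverting walk
around an activity center, $x_{t+1} = c + e^{-\phi}(x_t - c) +
\varepsilon_t$ with $\phi = 0.6$/day and stationary SD 200 m, chosen
because the stationary spread maps directly onto expected UD area. At the
season opening, high-risk females inflate their stationary SD by 1.47
(so the expected log-area contrast is $2\ln 1.47 \approx 0.77$), reverting
in the late season, and displace their center by 500 m; males carry a
response scale (default 0) reflecting the emulated system, where
depredation masks the vulnerable sex's population-level response. The
per-photo hunter count distribution is an assumption (no count model is
observable from photo summaries) and is flagged as such in `truth.yaml`.

Not emulated: within-site habitat selection, weather, natural-predator
movement, multi-year turnover, and hunter movement within sites. Passing
tests therefore demonstrate that the estimators and inference machinery
recover known truths under realistic sampling — not that real pheasant
data would satisfy model assumptions.

## Numerical choices and degenerate inputs

Grid padding below $3h$ is rejected rather than silently truncating mass;
all-identical points reject bandwidth estimation; parallel bearings are
flagged non-converged; camera days with zero photos are missing, not zero
pressure; aliased fixed effects are rejected with the offending columns
named; constant response matrices reject the PERMANOVA (zero total SS);
subsample cells with a single plot are carried deterministically. All
stochastic stages accept seeds, and identical configurations reproduce
byte-identical output tables end to end.

## Problem sizes used by the test suite

The validation suite runs the full recovery experiment at 12 individuals
per sex × risk-group cell (48 birds, ~1600 windows per replicate, 50
effect and 50 null replicates) with 60-cell grids, and the end-to-end
determinism check at 4 per cell — sizes chosen so the entire suite
completes on a single CPU in minutes while leaving the power of the
headline recovery test above 90%. The acceptance script runs the
full-scale default (25 per cell, 100 birds) once.

## Known limitations

* **Window pseudo-replication.** Successive moving windows share 10 of 11
  relocations, so window-level model rows are strongly dependent. Site and
  individual random intercepts do not absorb this, and the window models'
  REML standard errors are substantially too small: on zero-effect
  synthetic data the log-pressure coefficient's 95% CI excludes zero far
  more often than 5%, with no consistent sign. This is inherent to the
  overlapping-window design when fitted with independence-assuming mixed
  models (autocorrelation-aware corrections are deliberately out of scope,
  matching the analysis being reproduced); window-model significance flags
  should therefore be read as descriptive, and the seasonal (non-
  overlapping) models used for calibrated hypothesis tests. The seasonal
  models hold their nominal false-positive rate in the same experiments.
* The triangulation error model assumes independent von Mises bearing
  errors; bias from animal movement within a bearing set's 20-minute span
  is not modelled.
* Kernel home ranges at 10–25 fixes are upward-noisy; analyses are
  designed for contrasts between groups/seasons, not absolute area
  estimation.
* 26 October falls in neither the pre- nor the early-season definition;
  it is excluded rather than guessed into a season.
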