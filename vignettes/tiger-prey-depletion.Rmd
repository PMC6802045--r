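---
title: "Modelling tiger territories under spatially heterogeneous prey depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tiger territories under spatially heterogeneous prey depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tigerscape` is a spatially explicit, individual-based model of tiger
(*Panthera tigris*) territory and population dynamics in an isolated
protected area, coupled to an experiment engine that removes prey along
spatial gradients from the area border. This vignette documents the model,
its parameters, and the design decisions taken where the underlying model
family leaves details open.

## The landscape

Space is a raster of 250 m × 250 m cells (62,500 m² each), matching the
resolution of ungulate prey data for the Nepal lowlands. Each inside cell
carries a static *prey biomass production* value in kg/month. Two
landscapes are built in:

* **the stylized circle** — a disc of configurable area (default 1,000 km²,
  the size of many protected areas worldwide), every cell initialized to
  the Chitwan-average 4.84 kg/month. A cell is inside iff its centre falls
  within the analytic disc of radius $\sqrt{A/\pi}$, so the inside-cell
  count tracks the requested area to within rasterization error (< 1%).
* **a synthetic heterogeneous surface** — Gaussian-smoothed uniform noise,
  rescaled to the envelope reported for Chitwan National Park (minimum
  2.05, maximum 10.46, mean 4.84 kg/month/cell) by a monotone power
  transform whose exponent is solved so the realized mean matches exactly.
  This is a *synthetic stand-in*: it reproduces the value envelope and
  spatial autocorrelation of a real prey raster, but none of its geography
  (river corridors, grassland patches, asymmetric park shape), so analyses
  on it support qualitative statements only. Real rasters can be supplied
  as ESRI ASCII grids.

Every inside cell knows its Euclidean distance to the border, defined
cell-centre to nearest outside cell-centre (a virtual one-cell outside ring
beyond the raster edge keeps the field defined for masks that touch the
edge). This convention is unambiguous on a raster and is verified against a
brute-force all-pairs computation in the tests.

## Tigers

Agents are individual tigers with monthly ticks. Age classes: cub
(< 12 months), juvenile (12–23), transient (24–35), breeding age from 36
months (3 years). Annual survival (breeding male 0.8, breeding female 0.9,
dispersing/transient male 0.65, transient female 0.7, juvenile 0.9,
cub 0.6) is applied monthly as $s^{1/12}$; an annual breeding probability
$P$ becomes the monthly hazard $1-(1-P)^{1/12}$ (0.9 for 3-year-old
resident females, 1 for older). Litters have 2–5 cubs (probabilities 0.23,
0.58, 0.17, 0.02 — singletons do not occur), a 50:50 birth sex ratio, and a
gestation of 3 or 4 months with equal probability. Cubs and juveniles stay
in the natal territory and die if their mother dies. After a male takeover,
each cub of the deposed male's females dies with probability 0.79, each
juvenile with 0.24.

**Interbirth interval.** The model family does not state when a mother may
conceive again. A living offspring blocks its mother's conception until it
reaches `conception_block_age` (default 18 months); with a 3–4 month
gestation this reproduces the ~21.6-month interbirth interval observed in
Chitwan. Offspring remain dependent — they die with their mother, and are
exposed to infanticide — until 24 months. The window is configurable; a
24-month block lengthens the interbirth interval to ~27 months and lowers
the equilibrium population, a 12-month block does the opposite.

## Female territories

A territory is an exclusive, 8-connected set of cells anchored at an origin
cell. A female utilizes 10% of its prey biomass production; two intake
thresholds structure her behaviour, both from daily consumption rates
((kg/day × 365)/12): a basal-metabolic minimum of 76 kg/month (2.5 kg/day)
and a satiation maximum of 167.3 kg/month (5.5 kg/day).

* **Origin search.** At 36 months a female inspects all free cells within
  33 km of her natal cell and picks the one with the highest mean prey over
  its 8-neighbourhood (plus itself) having no cell of another female's
  territory within 2 km — enough open space to establish without immediate
  competition. Failing that she accepts a 1 km exclusion; failing that she
  dies (recorded as `no_territory`, a starvation-class death: the landscape
  is too crowded for her to feed herself).
* **Growth.** Each month she adds the adjoining free cell with the highest
  prey, at most 48 cells (3 km²) per month, until her intake first reaches
  the growth target. The default target is the satiation maximum: on the
  uniform circle this yields territories of ≈ 346 cells (≈ 21.6 km²), the
  only reading consistent with the emergent control territory size of the
  model family (stopping at the 76 kg/month minimum would give 9.9 km²
  territories). Establishment is *absorbing*: once the target is reached
  the female stops enlarging and only rearranges, re-entering growth only
  if her intake later falls below the minimum. Without this, depleted
  landscapes leave every female permanently below target, incumbents absorb
  all free cells, and recruitment collapses.
* **Adjustment and trimming.** An established female swaps her lowest-prey
  removable cell (never the origin; removal must keep the territory
  connected) for a strictly better free adjoining cell, at most 24 swaps
  (48 changed cells) per month — each swap strictly increases her prey sum.
  If her intake exceeds the satiation maximum (e.g., after winning contested
  cells) she sheds her lowest-prey removable cells while staying at or above
  it, freeing space for others.
* **Contests.** Each month, each pair of territories sharing a border
  contests with probability 0.25; the winner is drawn by a logistic
  function of the age difference, $p = 1/(1+e^{-k\,\Delta\text{age}})$ with
  $k = 0.5$ per year (older favoured), and takes the loser's highest-prey
  border cell, connectivity permitting.
* **Starvation.** A female whose growth is blocked (no free adjoining
  cells, or the hard cap of 960 cells) while her intake is below the
  76 kg/month minimum dies that month. There is no grace period.

## Males

Males disperse at 36 months. Any adult male below the cap of six females
claims the nearest unowned settled female within 66 km of his natal cell
(one per month); a male with no females and no unowned candidate challenges
the owner of the closest female, skipping males he has already lost to. The
challenger wins by the same logistic age rule; the winner takes all the
loser's females (truncated to six, surplus released), infanticide strikes
the transferred females' dependents, and the loser dies with probability
0.6 if he was a breeder (0.25 for a transient challenger dying after a
failed challenge) or re-enters dispersal. Breeding males additionally
absorb unowned females whose origin lies within 3 km of any cell of their
females' territories — the male's range encompasses his females'
territories, so the search radius is anchored there rather than at origins
(origin-to-origin distances are ≥ 2 km by construction and would make the
rule nearly inert).

## The monthly schedule

Phases, in a fixed order chosen so that resources settle before starvation
is judged and takeovers precede conception: (1) aging, (2) natural
survival, (3) orphan deaths, (4) female dispersal and origin search,
(5) territory growth/adjustment/trimming and female contests,
(6) starvation, (7) male dispersal, acquisition and challenges with
infanticide, (8) gestation, births and conception, (9) orphan sweep and
recording. Agents are processed in a fresh random permutation within each
phase; exact ties anywhere are broken uniformly at random from the run's
RNG stream, so a run is fully determined by its configuration seed.

Runs start with 14 breeding-age females and 7 males (ages uniform on
36–120 months), run 200 burn-in months, apply the depletion experiment
instantaneously to the landscape, and continue for 480 further months
(40 years, the time the model family reports for reaching a new
quasi-stationary state).

## The depletion engine

An experiment is (spatial function, landscape-level fraction, cell-level
fraction). The landscape level (5–25%) fixes the total prey removed; the
cell level (25–100%) fixes the share of a cell's *current* prey removed per
depletion event. Each pass visits all inside cells in a fresh random
permutation; a visited cell is depleted when a uniform draw falls below its
probability; passes repeat until the target is met, so cells can be hit
repeatedly. The final event is clamped to the residual, making the
landscape-level factor exact (the source description is silent on
overshoot; the clamp keeps the factor comparable across experiments). A
pass that removes nothing raises a non-convergence error.

The model family names its five distance functions but never prints their
equations; on normalized distance $d' = d/d_{max}$ we use

| function | $p(d')$ |
|---|---|
| exponential | $e^{-10 d'}$ |
| logarithm | $\max(0,\, 1-\log_{10}(1+9d'))$ |
| linear | $1-d'$ |
| inverse distance weighted | $1/(1+d')$ |
| 1-exponential | $1-e^{-10(1-d')}$ |
| random | $0.5$ (uniform over cells) |

All five distance forms are ~1 at the border, monotone non-increasing, and
reproduce the documented penetration ordering (exponential shallowest,
1-exponential deepest); the decay constants are calibrated only to that
ordering and are configurable. Whether the original random function
depleted every visited cell or a constant fraction is unstated; we use a
constant 0.5, which only rescales the number of passes.

## Moran's I

Spatial heterogeneity of prey is summarized by global Moran's I with queen
(8-neighbour) contiguity and row-standardised weights, computed by default
over the **whole raster rectangle** with zero prey outside the protected
area — the lattice the raster world actually is. On this convention the
undepleted uniform circle scores ≈ 0.93 (a flat disc on a zero background
is strongly autocorrelated) and every depletion lowers it; restricting to
inside cells (available via `include_outside = FALSE`) makes the statistic
blind to the area/background structure and near 0 for lightly-depleted,
nearly-uniform surfaces. Only the whole-rectangle convention reproduces the
value range and all monotone directions reported for this model family; a
constant surface raises an error rather than returning 0. One Moran's I per
experiment is taken from replicate 1's depleted landscape and applied to
all replicates, mirroring the family's analysis convention.

## Experiments and analysis

`build_design()` crosses 6 functions × 5 landscape levels × 4 cell levels
(120 experiments) × 32 replicates (3,840 rows) plus a separate 32-replicate
control block, with per-replicate seeds derived from a base seed;
`run_experiment_suite()` executes it resumably with per-row completion
markers and non-fatal per-row failures. Outcomes per replicate: final-tick
population, final-tick mean female territory (cells × 0.0625 km²), and the
adult-female starvation rate — the mean over the last 100 months of
(starvation-class deaths of adult females / adult females alive at the
month's start), months without adult females excluded.

`fit_outcome_models()` fits gamma log-link GLMs (Moran's I, territory
size), a negative binomial log-link GLM (population; dispersion by maximum
likelihood via `MASS::glm.nb`), and the Moran's-I-as-covariate variants,
with control replicates as the reference category and 90% Wald intervals.
Because the control level ties the three factors, two dummy columns are
collinear; factor levels are ordered so the landscape-5% and
random-function columns are the ones dropped, matching the family's
reported identification. Extinct replicates are dropped from territory
models and kept as zero counts in population models. Exponentiating a
coefficient multiplies the control mean: `exp_effect(20.51, 0.04)` ≈ 21.35.

## Problem sizes used by tests and the acceptance script

The full factorial at 32 replicates is a long-running batch; the shipped
checks use the sizes below, chosen to keep the emergent quantities at full
landscape scale while bounding wall-clock time:

* control emergence: 32 replicates of the full 1,000 km² circle, 680
  months each (this is also exactly what `scripts/acceptance.R` runs);
* factorial effects: a reduced subset — functions {linear, random} ×
  landscape {5%, 15%, 25%} × cell {25%, 100%} × 4 replicates — pooled with
  the 32 controls for the GLMs. The landscape-5% level is retained as the
  sacrificial collinear column so the identification matches the full
  design;
* depletion-engine properties: a 300 km² circle, 10 seeds per claim;
* scheduler unit tests: a 200 km² circle with shortened horizons.

## Known limitations

* The synthetic heterogeneous landscape shares only the statistical
  envelope of a real prey raster; quantitative results for any real park
  require its actual raster.
* Prey is static apart from the single depletion event: no seasonality,
  regrowth, or predation feedback, and no energetic cost of movement —
  territory size is bounded by the satiation ceiling rather than by travel
  costs.
* The scheduler's phase order, the contest/decay constants, the conception
  window and the Moran lattice convention are documented choices where the
  model family is silent; all are configurable, and the emergent control
  territory size and population are the empirical checks on the defaults.
* With 21 founders, individual replicates occasionally pass through an
  early bottleneck before reaching the quasi-stationary regime; replicate
  means are the meaningful quantity.
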