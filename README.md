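# tigerscape

Prey depletion is a leading threat to large carnivores, and inside
protected areas it is rarely uniform: people degrade prey along park
borders, or push deep inside to hunt. `tigerscape` is a spatially
explicit, individual-based model of tiger (*Panthera tigris*) territory
and population dynamics built to ask how the *spatial configuration* of
human-induced prey depletion — not just its total amount — shapes carnivore
space use and persistence in an isolated protected area. It is aimed at
spatial ecologists and protected-area planners who want a desk-scale,
fully reproducible experiment engine.

## The model in brief

Space is a raster of 250 m cells carrying static prey biomass production
(kg · month⁻¹ · cell⁻¹). Female tigers hold exclusive, 8-connected
territories: a dispersing 3-year-old picks an origin cell within 33 km of
her natal site (highest neighbourhood prey, no other territory within
2 km, relaxed to 1 km), then adds the best adjoining cell up to 48 cells
(3 km²) per month. With utilization *u* = 0.1 she needs an intake
*u*·Σ prey of at least *T*min = 76 kg/month (2.5 kg/day, basal
metabolism) to survive and stops enlarging at the satiation ceiling
*T*max = 167.3 kg/month (5.5 kg/day); adjacent females contest border
cells, with the winner drawn by a logistic function of age. Males
monopolize up to six females within 66 km of their natal site and fight
take-over challenges; infanticide strikes the deposed male's cubs (0.79)
and juveniles (0.24). Demography is stage-structured (monthly survival
*s*^(1/12) from annual class rates, litters of 2–5, 50:50 sex ratio,
3–4 month gestation).

A depletion *experiment* removes a landscape-level fraction (5–25%) of
total prey by sweeping the cells in random order and depleting each
selected cell by a cell-level fraction (25–100%) of its current prey,
with per-cell selection probability given by one of six spatial functions
of border distance *d* (on *d′* = *d*/*d*max):

| function | p(d′) |
|---|---|
| exponential | e^(−10 d′) |
| logarithm | max(0, 1 − log₁₀(1 + 9 d′)) |
| linear | 1 − d′ |
| inverse distance weighted | 1/(1 + d′) |
| 1-exponential | 1 − e^(−10 (1 − d′)) |
| random | 0.5, uniform over cells |

Sweeps repeat until the landscape target is met exactly, so cells can be
depleted repeatedly. Spatial heterogeneity of the resulting prey surface
is summarized by global Moran's I (queen contiguity, row-standardised,
computed over the raster rectangle with zero prey outside the area), and
outcomes across the factorial design — 6 functions × 5 landscape levels ×
4 cell levels × 32 replicates plus controls — are analysed with gamma and
negative binomial log-link GLMs against the control reference. See the
methods vignette (`vignettes/tiger-prey-depletion.Rmd`) for every design
decision.

## Worked example

```r
library(tigerscape)

circle <- make_circle_landscape(area = 1000, prey_per_cell = 4.84)
circle
#> landscape_grid: 147 x 147 cells (250 m side), 16005 inside (1000.3 km2)
#> prey kg/month/cell: min 4.84  mean 4.84  max 4.84  total 7.746e+04
#> border distance: max 17847 m

spec <- depletion_spec("logarithm", landscape_fraction = 0.25,
                       cell_fraction = 0.5, seed = 1)
res <- apply_depletion(circle, spec)
res
#> depletion_result: removed 1.937e+04 kg/month in 2 pass(es); 7727 cells hit (max 2 times)
morans_i(res$grid)
#> [1] 0.746

run <- sim_run(sim_config(landscape = circle, seed = 1))
compute_outcomes(run)
#>   population territory_km2 starvation_rate morans_i
#> 1        150      19.68934     0.005870922 0.958561
```

The depletion removed exactly 25% of the 77,460 kg/month standing prey
(19,370 kg) in two sweeps, and lowered Moran's I from 0.959 (the flat
disc) to 0.746. The 680-month control run ends with 150 tigers whose
breeding females hold territories of 19.7 km² on average and starve at
about 0.006 adult females per month — the emergent quantities the
experiments perturb.

A command-line front end for single runs, depletion-only experiments,
factorial suites, GLM analysis and synthetic-landscape fixtures is
installed at `inst/cli/tigerscape` (see `?tigerscape_cli`).

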