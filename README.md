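# sealselect

Foraging-habitat-selection analysis for diving central-place foragers —
gray and harbor seals tracked with GPS/GSM tags carrying dive recorders and
wet/dry sensors. The package turns the three raw tag streams (20-min GPS
fixes; dives with duration, maximum depth and nine intermediate depth
points; a wet/dry series) into a resource-selection analysis around the
tagging colony, and ships a synthetic seascape/track generator with a known
ground-truth selection surface so every stage is testable by parameter
recovery.

It is written for movement ecologists who want the full pipeline —
foraging-dive classification, trip segmentation, use-availability design,
smooth selection models, prediction maps, and home-range overlap — behind
small composable functions rather than a monolith.

## The method

**Foraging dives.** Dive shape is scored with the Time Allocation at Depth
index. With `A` the trapezoidal area under the depth profile, `D` the
maximum depth, `T` the duration and `v_max` the maximum vertical transit
speed,

    TAD = (A − A_min) / (A_max − A_min),   A_min = D²/v_max,   A_max = D·T − D²/v_max,

so 0 marks extreme V-dives (transit) and 1 extreme square dives (benthic
foraging). Per individual, after dropping dives < 3 m or < 30 s, the 25%
highest-TAD dives are kept and the 10% slowest-descending of those removed
(resting), flagging ≈ 22.5% of dives as foraging.

**Use-availability design.** Each individual's foraging dives (response 1)
are contrasted with two pseudo-absences per dive (response 0) sampled
uniformly inside the colony's availability region: the 100% minimum convex
polygon of foraging dive locations, scaled to three times its area and
clipped to the continental shelf and to sea.

**Selection model.** A binomial GAMM with logit link:

    logit P(use) = α + s(bathymetry) + s(tidal current) + s(dist. to shore)
                   + s(least-cost dist. to last haulout) + sediment
                   + (1 | individual)  [+ (1 | site) in global mode]

with cubic-regression-spline smooths (k = 5), the sediment reference level
forced to the dominant class, REML smoothing, VIF screening, AIC model
selection, and covariate importance as the drop-term decomposition of the
explained deviance. Distances to the last haulout are geodesic *at sea*
(shortest paths over an 8-connected sea-cell graph), never through land.

**Spatial usage.** Trip duration and maximum at-sea extent are compared
across colonies (Shapiro/Bartlett gate → ANOVA/Tukey or
Kruskal–Wallis/Dunn), colony-size and latitude effects are tested with
site-random-intercept mixed models compared by AIC, and home-range overlap
is the Bhattacharyya affinity `BA = Σ √(p₁·p₂)` between 95%-truncated
kernel utilization distributions of foraging dive locations.

## Worked example

```r
library(sealselect)

sc   <- make_seascape(seascape_params(extent_km = 100, cell_km = 2,
                                      n_haulouts = 2), seed = 1)
sc
#> <seascape> 50 x 50 cells (2 km), 20% land, 2 haulout site(s), 4 sediment class(es)

pref <- true_preference(b_bathy = -0.02, b_haulout = -0.08, phi = 0.5)
sim  <- simulate_seals(sc, pref, n_seals = 4, n_trips_per_seal = 6, seed = 2)
sim
#> <sim_output> 4 seals, 1865 fixes, 417 dives (50.8% foraging), 60 wet/dry rows

run <- run_pipeline(default_config(seed = 1))
make_report(run)
#> === sealselect run report ===
#> species: gray   mode: colony   seed: 1
#> data: 1865 fixes, 417 dives
#> dives: 417 -> 309 prefiltered -> 72 foraging (23.3%)
#> availability: MCP 1928 km2, buffer 5784 km2, clipped 3380 km2; 144 pseudo-absences
#> model: ED 44.1% (AIC 180.0); importance: bathy 31.1%, tidal 12.1%, dist_shore 6.6%, dist_haulout 45.9%, sediment 4.2%
#> trip stats: parametric branch, omnibus p = 0.5305 over 24 trips
#> overlap: 6 pairs, BA 0.80 +/- 0.10
```

Reading the report: 417 simulated dives prefilter to 309 usable ones, of
which the two-stage rule flags 72 (23.3%, the expected ≈ 22.5% at these
group sizes) as foraging. The availability buffer is exactly three times
the MCP area before shelf/land clipping. The fitted selection model
explains 44% of the deviance, and — as planted in the generating
preference, which penalized depth and distance from the haulout — the
distance-to-haulout and bathymetry terms carry most of the importance. The
trip-metric comparison between the two haulout sites finds no difference
(the generator treats them identically), and the seals' 95% utilization
distributions overlap strongly (BA 0.80) because all individuals share one
preference surface.

Individual stages are plain functions if you want them à la carte:
`detect_haulouts()`, `segment_trips()`, `tad_index()`,
`classify_foraging()`, `least_cost_distance()`, `mcp()`,
`availability_region()`, `sample_pseudo_absences()`,
`fit_selection_model()`, `term_importance()`, `predict_map()`, `kde_ud()`,
`bhattacharyya()`, `compare_sites()`, `colony_size_models()`. A thin CLI
(`inst/cli/sealselect.R`) wraps simulate/run/report for shell use.

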