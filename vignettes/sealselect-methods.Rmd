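---
title: "Methods: foraging habitat selection for diving central-place foragers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foraging habitat selection for diving central-place foragers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealselect)
```

`sealselect` analyses where diving central-place foragers — gray seals
(*Halichoerus grypus*) and harbor seals (*Phoca vitulina*) are the motivating
species — choose to forage at sea, from three tag data streams: GPS fixes
attempted on a 20-minute schedule, dive records (start/end time, maximum
depth, duration and nine intermediate depth points), and a wet/dry sensor
series. This vignette explains each stage's model and assumptions, the
tunable parameters, the numerical choices, and what the bundled synthetic
generator does and does not emulate.

## 1. Dive classification

### The TAD index

Benthic foraging dives are "square" (U-shaped): most of the dive is spent
at the maximum depth. The Time Allocation at Depth (TAD) index scores this
shape on $[0, 1]$. For a dive of duration $T$ and maximum depth $D$, with
$A$ the trapezoidal area under the piecewise-linear depth profile (the two
surface endpoints plus the nine recorded interior points), and a maximum
vertical transit speed $v_{\max}$:

$$
A_{\min} = \frac{D^2}{v_{\max}}, \qquad
A_{\max} = D\,T - \frac{D^2}{v_{\max}}, \qquad
\mathrm{TAD} = \frac{A - A_{\min}}{A_{\max} - A_{\min}},
$$

clamped into $[0,1]$. $A_{\min}$ is the fastest possible V-dive (straight
down and up at $v_{\max}$), $A_{\max}$ the fastest square dive, so 0 marks
extreme V-dives and 1 extreme U-dives. The index is only defined when the
animal could physically reach $D$ and return within $T$, i.e.
$2D/v_{\max} < T$; dives violating this are flagged unscorable and
excluded. At exact equality the denominator vanishes and the limiting
V-dive value 0 is returned. Pre-clamp excursions outside $[0,1]$ (profiles
implying transit faster than $v_{\max}$) are counted in the package log.

`v_max` defaults to 2 m/s, a conservative bound for both species;
`estimate_v_max()` offers a per-deployment alternative (99th percentile of
observed descent speeds). Vertical descent speed is defined as the depth of
the first interior profile point divided by its time offset — the
surface-to-first-inflection slope. This is one of several defensible
definitions (the full descent phase is another); it is isolated behind one
function so alternatives are swappable.

### Two-stage foraging rule

Per individual (inter-individual variability in diving is substantial, so
quantiles are never pooled): after excluding dives shallower than 3 m or
shorter than 30 s (strict inequalities; boundary dives are kept), stage 1
keeps the $\lceil 0.25\,n \rceil$ highest-TAD dives; stage 2 removes the
$\lfloor 0.10\,k \rfloor$ lowest-descent-speed dives among those (slow
U-dives are more likely resting than foraging). About 22.5% of each
individual's dives are flagged. Rounding directions are fixed
(ceiling then floor) so counts are deterministic, and ties break toward the
earlier start time. Individuals with fewer than 8 scored dives are
unclassifiable — quantiles are meaningless — and get `NA` flags with a log
entry.

Dive locations are linearly interpolated at the dive's midpoint time
between the bracketing GPS fixes (bracketing gap capped at 6 h by default);
start- or end-time interpolation would differ by at most a few hundred
metres at these fix rates.

## 2. Haulout events and trips

A haulout event opens at the start of a maximal dry run strictly longer
than 10 minutes and closes at the first wet run reaching 40 s; shorter wet
splashes do not split an event. The event start is stamped at the beginning
of the dry run — this choice affects event duration only, never trip
topology. Trips are the intervals between consecutive events of a seal that
contain at least one strictly at-sea fix; fixes at the boundary instants
belong to the haulout.

Tracks are regularized to a 20-minute lattice anchored at the departure by
straight-line interpolation (never extrapolated past the last fix), which
removes the sampling bias toward areas where seals surface often. Trips
shorter than 3 h (strict) are dropped as haulout-vicinity excursions, trips
departing in the species' breeding/molt months are dropped (gray seals:
September–February; harbor seals: June–September; the departure month
defines a trip's season), and in gray-seal mode only trips departing *and*
arriving at the tagging colony are kept — gray seals also travel between
colonies, harbor seals are strongly site-faithful, so harbor mode leaves
`return_only` off.

Trip metrics are duration (arrival-haulout start minus departure-haulout
end) and maximum extent: the largest *at-sea least-cost* distance from the
departure haulout over the regularized track, consistent with the geodesic
distance covariate below (straight-line distance is available behind a
flag).

## 3. Spatial backbone

All synthetic worlds live on a planar kilometre grid; every operation
declares its coordinate mode. Least-cost (at-sea geodesic) distances are
shortest paths over the 8-connected graph of sea-cell centers (cardinal
edges one cell, diagonals $\sqrt2$); they can exceed the straight-line
distance by at most ~8% in open water, the standard octile-discretization
bound, and never undercut it. 16-connectivity is available where that bound
matters. Distance to shore is the straight-line distance to the nearest
coastline vertex (one vertex per land/sea cell edge, so the error is below
half a cell).

The availability region for the use-availability design is built from the
100% minimum convex polygon (MCP) of all foraging dive locations of the
colony's seals: the MCP is scaled about its area centroid by $\sqrt3$ per
axis — exactly tripling its area, the reading of "three times the size"
that triples available habitat (linear scaling is retained behind a flag
for sensitivity runs) — then clipped to the continental shelf and to sea.
The clipped region is represented on the analysis grid and its area is the
clipped cell count times the cell area. Pseudo-absences are sampled
uniformly over the clipped region by rejection from the scaled polygon's
bounding box, two per foraging dive per individual, with no covariate
filtering whatsoever: they represent availability, not absence of use. A
rejection acceptance below 1% aborts (degenerate sliver region).

## 4. The habitat-selection model

The use-availability table contrasts foraging dives (response 1) with
pseudo-absences (response 0) per individual. The model is a binomial GAMM
with logit link:

$$
\mathrm{logit}\, P(y_i = 1) = \alpha + \sum_j f_j(x_{ij}) +
\beta_{\mathrm{sed}(i)} + b_{\mathrm{ind}(i)} \,(+\, b_{\mathrm{site}(i)}),
$$

with cubic-regression-spline smooths $f_j$ (basis dimension `k = 5` by
default — enough for the monotone-to-unimodal responses seen in these
covariates while keeping 32-candidate selection cheap; `k` is configurable
and stamped into outputs) of bathymetry, tidal current speed, distance to
shore and least-cost distance to the last haulout; a categorical sediment
effect whose reference level is forced to the over-represented class so
that contrasts are stated against the dominant habitat; and ridge-penalized
random intercepts per individual (plus per site in the pooled "global"
mode). Smoothing parameters and random-effect variances are estimated by
REML. In global mode a systematic 1-in-3 subsampling of each individual's
dive rows (with pseudo-absences reduced pro rata to keep the 1:2 balance)
mitigates the convergence cost of pooled fits; on simulated data this moves
coefficients by less than one standard error.

Collinearity is screened by VIFs ($1/(1-R^2_j)$ from regressing each
continuous covariate on the others plus dummy-coded sediment), report-only
with a warning threshold of 5. Candidate term sets are compared by AIC
(effective degrees of freedom of penalized terms); candidates are fitted
with shrinkage smooths so that comparison is not dominated by unpenalized
null-space noise, ties break toward fewer terms, and failed candidates are
recorded while selection proceeds over the survivors. AIC retains a null
term whenever its chance deviance gain exceeds twice its degrees of
freedom (probability $\approx 0.16$ per term), so selection consistency
against noise covariates is bounded near $P(\chi^2_k < 2k)$ — a property
of AIC itself, not of the implementation; the tests assert bounds derived
from that distribution.

Covariate importance is a drop-term decomposition: each term's raw
importance is the loss of explained deviance
($100\,(1 - D_{\mathrm{model}}/D_{\mathrm{null}})$) when it is refitted
out, negative losses are floored at zero (and logged), and shares are
normalized to 100%. A partial-prediction-variance alternative would rank
terms similarly for monotone effects; the drop-term form was chosen because
it is defined for categorical terms without an arbitrary scale.

Prediction maps evaluate the population-level inverse-logit prediction on
every sea cell with random intercepts set to zero, with approximate
pointwise standard errors on the link scale. The distance-to-last-haulout
covariate has no unique value on a map; it is surrogated by the least-cost
distance to the *nearest* colony haulout. Cells whose covariates leave the
fitted range are flagged extrapolated per cell rather than masked.

## 5. Home-range overlap

Utilization distributions are product-Gaussian kernel densities evaluated
on a declared grid and normalized over cells. The bandwidth rule is
unstated in the field's common tooling defaults, so the normal-scale
(reference) rule $h = 1.06\,\hat\sigma\,n^{-1/5}$ per axis is the default
and is recorded in the UD object. The 95% volume contour is the smallest
highest-density cell set reaching 0.95, with equal-density ties admitted in
row-major order (this matters only for degenerate UDs); the UD is truncated
to it and renormalized. The Bhattacharyya affinity
$\mathrm{BA} = \sum_{\text{cells}} \sqrt{p_1 p_2}$ is computed on the
95%-truncated, renormalized UDs of both individuals evaluated on a common
grid (union bounding box; both UDs re-evaluated there, never resampled);
untruncated BA is available behind a flag. BA is 0 for complete
segregation, 1 for complete overlap, symmetric, and stable to grid
refinement on smooth UDs (halving the cell size moves it by < 0.02).

## 6. Trip statistics

Trip duration and maximum extent are log-transformed. Shapiro–Wilk per
site and Bartlett across sites gate, at $\alpha = 0.05$, a parametric
branch (one-way ANOVA + Tukey HSD) against a nonparametric branch
(Kruskal–Wallis + Dunn's pairwise rank test with tie correction). Dunn's
p-values are Holm-adjusted by default (the adjustment is configurable).
Colony-size effects are tested by three linear mixed models of each log
metric — seal count + site random intercept, latitude + site intercept,
and both — fitted by maximum likelihood for AIC comparability, with Wald
p-values for the winner's fixed effects. Trips are treated as independent
within and across individuals; a seal-level cluster bootstrap can be
layered on top by resampling seals, but is not part of the standard
output.

## 7. The synthetic generator

`make_seascape()` builds a coastal band of land whose outline wiggles with
a complexity parameter, bathymetry that deepens monotonically offshore
(with correlated noise and a floor of 2 m at sea-cell centers, which sit at
least half a cell offshore), spatially autocorrelated categorical sediment
(quantile bins of a smoothed field), a nonnegative smooth tidal field
(mean ≈ 0.7 m/s), the shelf mask (sea no deeper than the cutoff), and
haulout sites on coastal sea cells of the main sea component. Everything is
deterministic given `(params, seed)`.

`simulate_seals()` draws each trip's foraging-dive cells *iid from the
normalized true selection surface* and routes the seal through them by
least-cost sea paths (20 minutes per cell step), so dive placement realizes
the ground-truth preference exactly — the contrast the use-availability
design estimates — and at-sea steps can never cross land. Foraging dives
are square-profiled with descent speeds of 0.8–1.4 m/s and maximum depths
at 80–98% of the local bathymetry; transit dives are V-shaped, shallower
(20–50% of bathymetry), and placed along the route. Wet/dry series are
emitted as state changepoints with haulout bouts of 30–180 min and optional
sub-40-s wet splashes that must not split detected events. Fixes are
thinned by Bernoulli dropout (default 20% — a convention, since tag fix
success is not something the analysis depends on) with bout endpoints
always kept, as tags transmit reliably when dry or surfacing.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: location error (fixes are exact up to
within-cell jitter), tidal-phase dynamics (the tidal covariate is a static
strength field, matching the analysis' use of phase-averaged currents),
prey fields, behavioural states beyond the U/V dichotomy, and
autocorrelated step selection (dive sites are conditionally independent
given the surface, which makes recovery tests exact multinomial nulls but
understates the serial dependence of real tracks).

## 8. Problem sizes and numerical choices

The shipped tests run the generator at 40×40–60×60 cells with 2-km cells,
2–6 seals and up to ~6,000 dives; recovery tests fit at n = 6,000
use-availability rows over 25 replicates, and calibration tests run 500
null replicates of the omnibus comparison — sizes at which every
distributional claim in the test suite has adequate power while the whole
suite stays desk-scale. Other conventions: ESRI ASCII grids are the raster
interchange format; polygons use the shoelace area; rejection sampling is
the uniform sampler over clipped regions; REML fits are deterministic given
the data, so pipeline reruns with the same config are bit-identical; and
every stochastic stage takes an explicit seed derived from the run seed.
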