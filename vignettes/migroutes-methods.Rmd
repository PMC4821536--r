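---
title: "Seasonal ranges and migration routes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal ranges and migration routes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migroutes)
```

`migroutes` implements an end-to-end workflow for GPS telemetry of migratory
ungulates: screening raw relocations, partitioning each animal-year into five
behavioural seasons (winter, spring migration, calving, summer, fall
migration), estimating population seasonal ranges with fixed-kernel
utilization distributions (UDs), mapping migration corridors with Brownian
bridge movement models (BBMM), and quantifying between-year site fidelity and
within-year seasonal separation. This vignette explains the models, the
tunable parameters, the numerical choices, and what the synthetic-data tests
do and do not demonstrate.

All coordinates are metres in a planar equal-area projection (an Alaska
Albers, EPSG:3338-like frame is the intended default), so areas in km^2 are
meaningful without further transformation. Timestamps are UTC.

## Screening

Two filters clean raw fix tables.

**Gross outliers.** A fix more than 100 km (configurable) from its
time-adjacent retained neighbours — both neighbours for interior fixes, the
single neighbour at the ends — is a positioning blunder. Removal is iterative,
worst first, recomputing adjacency after each removal, so back-to-back
blunders displaced in different directions are peeled off one at a time. Two
blunders displaced to the *same* spurious location would shield each other;
such co-located pairs are not produced by the error model we emulate and
survive this filter by design.

**Movement spikes.** Over triples of successive fixes, the middle fix is
removed when the track reverses bearing by at least 150 degrees and both legs
imply speeds above 1.5 km/h. The speed threshold is the biological limit used
in arctic caribou screening; the reversal angle operationalizes the
"out-and-back" pattern that field analysts would otherwise flag visually.
Only the middle fix of a spike is removed. Both filters are idempotent and
return subsequences of the input.

**Thinning.** `thin_by_interval()` greedily keeps fixes at least 47 h apart.
On a regular 5-h summer schedule this retains exactly 1 of 10 locations, which
is how summer and winter samples are made commensurate before kernel
estimation.

## Season segmentation

Published workflows classify seasons by visual inspection of plotted
trajectories. `migroutes` replaces that judgement with explicit rules so the
partition is deterministic and configurable:

* **Directedness.** Net displacement is measured over a window (default 4
  days) *centred* on each fix. Migration starts at the first fix in the
  seasonal search window whose displacement exceeds a trigger (default 20 km)
  with mean heading within ±60 degrees of the migration axis (north for
  spring, south for fall; the axis is configuration for other geographies).
  Centring the window matters: a forward-anchored window systematically dates
  both boundaries ~2–3 days early, while the centred version is symmetric and
  biases boundaries by only about half a day.
* **End of migration.** The first subsequent time at which the rolling
  displacement stays below the trigger for a quiescence period (default 5
  days), or the calving onset if that comes first.
* **Total displacement.** A candidate is only accepted if it carries the
  animal at least 50 km from start to end. This cheaply rejects directed
  residency excursions that would otherwise trigger spurious migrations.
* **Search windows.** Spring is sought in roughly March–mid-June, fall in
  August–November, calving onsets in June 1–14 — the months prior studies
  report for arctic herds; these windows play the same role as the "initial
  step" priors a human classifier would use, and are configuration.

**Calving** is the earliest interval of at least 10 days (at most 14) whose
onset falls in the first two weeks of June and whose occupied area stays
below 1.5 km^2. The occupied area is the minimum convex polygon of the fixes
in the rolling window; because a perfectly straight path has zero hull area,
confinement additionally requires the window's diameter not to exceed that of
a disc of the threshold area (~1.4 km). Animals without a detected
confinement have their summer opened at the population mean calving end date.

**Fall start clipping.** Summer ranges are large and fall migration may begin
by crossing much of the summer range. To keep routes distinct from ranges,
the fall route starts at the first fix outside the 80% isopleth of that
year's pooled summer range — which is why the pipeline estimates summer
ranges between two segmentation passes.

## Fixed-kernel seasonal ranges

The UD estimator is an isotropic bivariate Gaussian kernel with a single
scalar bandwidth chosen by likelihood cross-validation (CVh): the bandwidth
maximizing the leave-one-out log-likelihood. The optimizer is a 50-point
log-spaced scan refined by golden-section search within the bracketing
interval, which agrees with a dense grid search to well under 1%. Bandwidth
selection on very large pooled samples uses a systematic subsample (cap 2000
points) to bound the quadratic pairwise-distance cost; KDE evaluation always
uses all points.

Per-season, per-year fixes are thinned to ≥47 h per animal and pooled across
individuals; the pooled UD's 90% isopleth is the seasonal range and the 80%
isopleth feeds fall-start clipping. UDs are discretized on a 500-m grid
(commensurate with the route grid) with the origin snapped to cell-size
multiples so all grids of one analysis share cell boundaries. Cell mass is
kernel density at the cell centre times cell area, renormalized; the grid is
built with a 4-bandwidth margin and a warning fires if less than 99.9% of the
kernel mass is captured.

**Isopleths** are highest-density cell sets: cells sorted by mass (ties
broken deterministically in row-major order), accumulated until the target
level. Nesting (80% within 90% within 95%) holds by construction; on an
analytic Gaussian UD the 90% region's area matches the closed form
2*pi*h^2*ln(10) to a fraction of a percent.

## Brownian bridge migration routes

Conditional on consecutive fixes z1, z2 separated by time T, the bridge
position at fractional time a is Gaussian with mean (1-a) z1 + a z2 and
variance T a (1-a) sigma2_m + (1-a)^2 delta^2 + a^2 delta^2. The motion
variance sigma2_m (m^2/s) is estimated per migration path by maximizing the
likelihood of every second fix under the bridge between its neighbours;
delta is the location-error SD, default 30 m (collar accuracy in the emulated
design was field-verified only as within 100 m, so delta is configuration).

The route UD is the time-weighted average over all inter-fix segments and a
midpoint discretization of a (default 10 steps per segment) of the bridge
density. Each Gaussian's cell mass is integrated exactly using the separable
normal CDF rather than approximated by the centre density: with location
error smaller than the 500-m cell the centre approximation misstates tail
cells by factors of 2–3, while the exact integral matches a 10^6-sample
Monte-Carlo binning oracle at the binomial noise floor. Segments with gaps
above `max_gap_h` (default 8 times the 5-h summer schedule in the pipeline)
are excluded: a bridge over a multi-day gap is uninformative. Population
routes are unweighted cell-wise means of the individual route UDs — each
animal contributes equally regardless of its fix count — and multi-year
composites count, per cell, the years whose 95% route isopleth covers it.

## Movement metrics and the distance correction

Mixed schedules under-measure path length: the chord between fixes T hours
apart is shorter than the path a 5-h schedule would have traced. The
correction adds CF(T) = exp(a + b*T) metres to an observed T-interval
distance. Published coefficients (spring a = -0.94, b = 2.36; fall a = -1.10,
b = 2.42) are shipped, but the unit of T in the printed formulas is
ambiguous — taken literally in hours they give astronomically large
corrections at 47 h — so models carry a declared `time_unit` (default: T
rescaled by the 47-h winter interval) and `calibrate_correction()` is the
primary path for any real dataset: it removes fixes from 5-h tracks to create
10–50 h gaps in 5-h steps, measures the mean shortfall (path minus chord) at
each gap, and fits log shortfall linearly in T with coefficient standard
errors.

A caution documented here deliberately: the exponential-in-T family is an
*approximation*. For a correlated random walk the true mean shortfall grows
roughly polynomially in T, so the fitted curve can deviate from held-out
shortfalls by tens of percent at the gap extremes even when the fit is
exact at the centre. The tests therefore verify the shortfall measurement and
the regression against exact oracles, and the prediction only to within a
factor of two; no tighter claim would be honest for this family.

Velocities are computed per consecutive-fix vector on corrected distances,
expressed per 5 h, averaged within each migration path, then summarized per
season as mean, SD and a normal-theory 95% CI (mean ± 1.96 SD/sqrt(n)); the
CI construction for the emulated study is not documented, so the plain normal
interval is used.

## Overlap, fidelity and composites

Isopleth regions live on congruent rasters, so intersection and union areas
are exact cell arithmetic. The overlap denominator is the union: percent
overlap = 100 |A∩B| / |A∪B|. This is the only convention consistent with the
one fully printed example in the emulated study (14,781 km^2 of 84,543 km^2 =
17.5%); the printed per-year figures never state their denominator, so both
areas are reported and the union convention is applied uniformly.
Site fidelity is the percent overlap between the same season's ranges in
consecutive years; seasonal separation is the within-year summer–winter
overlap. Years-of-use composites report the percent of the union area covered
in exactly 1..n years; the percents partition the composite and sum to 100.

## The synthetic trajectory generator

No public telemetry reproduces the emulated study, so the generator is a
first-class module with known ground truth. One simulated animal-year is:

* **Winter residency** around a winter centroid: a discrete-time
  mean-reverting (Ornstein–Uhlenbeck-style) walk, stationary SD 5 km,
  correlation time 72 h. The within-range movement model and its scale are
  free parameters of the generator, not estimates of any herd's behaviour.
* **Spring migration** toward a calving site near the summer centroid
  (centroids 250 km apart along the north–south axis by default). Calving
  onset is drawn in June 1–4; the mean migration start day (default day 134)
  anchors the timing and implies the travel speed, clamped into the 7–24
  km/day envelope reported for migrating caribou; a 0.5–1.5 day settling
  period at the site is still labelled spring migration. A configuration
  whose spring migration could not finish by June 14 even at top speed is
  rejected.
* **Calving confinement**: 10–14 days of independent positions in a 300-m
  disc (occupied area ~0.28 km^2, comfortably under the 1.5 km^2 criterion).
* **Summer residency** around the summer centroid, then **fall migration**
  back to the winter range starting around day 259 (mid September) at 15–24
  km/day — faster than spring, reproducing the reported asymmetry (fall
  shorter and more rapid than spring).
* **Sampling design**: fixes every 5 h in May–October and every 47 h in
  November–April, 2% independent fix failure, isotropic 30-m GPS error.
  Per-animal range offsets (SD 10 km) persist across years; population-level
  annual shifts are larger for winter (SD 15 km) than summer (SD 2 km), which
  is what makes simulated winter fidelity lower than summer fidelity.
* A configurable fraction of animals are **residents** occupying a single
  year-round range between the two centroids, with no migration or calving
  labels.

Determinism: per-animal, per-year and per-animal-year seeds are derived from
the configuration seed, so the same `sim_config` reproduces bit-identical
tracks, and an animal's persistent traits do not depend on how many other
animals are simulated.

`inject_outliers()` adds the two error classes screening removes: gross
outliers displaced 150–250 km perpendicular to the migration axis (hence
>100 km from every clean fix by construction) and spikes displaced by twice
the distance that makes both legs exceed 1.5 km/h for the local fix interval.
Spikes are placed only where both adjacent gaps are at most 6 h: a
qualifying spike over a 47-h gap would be a 70-km displacement, i.e. a gross
outlier, not a spike.

**What passing tests show — and what they do not.** The generator produces
clean phase transitions, isotropic stationary ranges and straight-ish
corridors. Real caribou tracks have insect-harassment aggregations, terrain-
and snow-driven route curvature, heteroscedastic fix failure, and ambiguous
part-year migrants. Recovery rates measured here (e.g. ~98% per-fix label
agreement, spring-interval temporal Jaccard 0.87–0.97) are therefore upper
bounds on what the same rules would achieve on field data, and the
segmentation defaults (window 4 d, trigger 20 km, sector ±60°, quiescence
5 d, minimum displacement 50 km) should be re-tuned against expert labels for
any new system.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, by choice, at scales a
laptop handles in minutes: populations of 25 animals over 2 years (50
animal-years, ~50,000 fixes) for segmentation recovery, 200 bridge segments
for variance recovery, a 10^6-sample Monte-Carlo oracle for one bridge UD,
and 500-m grids over a ~300 km arena for ranges and routes. Key numerical
conventions: grid origins snapped to cell-size multiples; half-open cell
membership; row-major tie-breaking at isopleth boundaries; isopleth level 1.0
returns exactly the positive-mass cells; optimizers are bounded scalar
searches (coarse log-spaced scan plus golden-section refinement) for both the
CVh bandwidth and sigma2_m, with degenerate inputs (coincident points,
motionless segments) raising errors or collapsing to the search bound as
appropriate.

## Known limitations

* Winter spans the calendar-year boundary; the pipeline pools each calendar
  year's early-winter (January–April) and late-winter (November–December)
  fixes into that year's winter range rather than splitting winters at
  January 1. With year-round simulated data the difference is immaterial, but
  for field data with partial years the convention matters.
* Co-located clustered blunders can survive the gross-outlier filter (above).
* The correction-factor family is misspecified for strongly tortuous paths
  (above).
* No probabilistic behavioural-state model is attempted: the segmentation is
  a deterministic surrogate for expert labelling, not a hidden Markov model,
  and offers no uncertainty statement on boundary placement.
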