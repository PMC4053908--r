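---
title: "Methods: simulating population commuter exposure to NO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating population commuter exposure to NO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(no2commute)
```

## 1. The model

`no2commute` estimates long-term (annual-mean) exposure to NO2 during
commuting for a population with geocoded travel diaries, and quantifies how
that estimate depends on the spatial resolution of the air pollution surface
used. The exposure model is a time-activity overlay:

* Each **leg** (contiguous trip part with one travel mode) is routed on a
  street network and overlaid on an annual-mean raster. Its concentration is
  the length-weighted mean of the traversed cells,
  $$C_{leg} = \frac{\sum_c C_{grid}(c)\,\ell_c}{\sum_c \ell_c},$$
  where $\ell_c$ is the exact length of the leg inside cell $c$ (computed by
  clipping the polyline against the cell edges, not by sampling).
* Annual rasters carry no diurnal information, so each leg is scaled by a
  **temporal adjustment factor**: the ratio of the annual weekday mean of
  its start hour to the overall annual weekday mean at a monitoring station —
  a street station for legs classified as main roads ($ratio_{m,h}$), an
  urban background station for side streets ($ratio_{s,h}$).
* Per subject, with waits between legs included,
  $$E_{subject} = \sum_{legs} C_{leg}\, r\, t_{leg} +
                  \sum_{waits} C_{wait}\, r_w\, t_{wait},$$
  time-weighted exposure $= E_{subject} / \sum t$ (µg m⁻³), which coincides
  with the duration-weighted mean concentration $C_{subject}$.
* **Dose** proxies inhaled amount by scaling each leg's cumulative exposure
  with a ventilation ratio relative to sitting transport: 1.7 for walking,
  2.0 for bicycle, 1.0 for motorized and public transport. No body-weight
  scaling is applied (no such covariates exist in the modelled diaries).

The printed forms of the subject-level equations in the source material are
not machine-readable; we define $C_{subject}$ as the duration-weighted mean
and $E_{subject}$ as the cumulative sum, the unique pair satisfying the
stated identity "time-weighted exposure = exposure / total duration".

## 2. The synthetic world

No public release of the original travel diaries, networks or pollution
surfaces exists, so every input is generated with known ground truth. The
generator's defaults are the stated study conditions, chosen once:

| Parameter | Default | Why |
|---|---|---|
| background_level | 23.5 µg m⁻³ | reported suburban background annual mean |
| grid_sizes | 25, 50, 100 m | the three emulated model resolutions |
| n_subjects | 258 | the within-city comparison sample size |
| mode_shares | walk .275, bike .306, motor .092, public .327 | the reported within-city main-mode split, renormalised over the four modelled modes |
| trips/day | 2 (84%), 4 (16%) | reported two-trip share |
| start times | N(07:00, 40 min), N(17:00, 40 min) | commutes concentrated in the 6–8 am / 4–6 pm rush hours |
| road_increment | 30 µg m⁻³ | plausible kerbside NO2 elevation for a low-pollution European city; puts street-station means near 50 µg m⁻³ |
| side_increment_factor | 0.5 | side streets carry roughly half the traffic signal; see §3 |
| decay_length | 60 m | typical near-road NO2 decay scale |
| noise_sd | 2.35 µg m⁻³ | 10% of background, for 30-min station values |
| n_weekdays | 261 | weekdays in one year |
| mode speeds | 5/15/30/20 km h⁻¹ | walk/bike/motor/public; the diaries report durations but do not model them, so durations follow from routed length |
| waits | uniform 0–10 min | at public-transport interchange nodes |

The latent concentration field is
$$f(x,y) = \text{background} + \text{road\_increment}\cdot
\max_k w_k\, e^{-d_k/\lambda},$$
with $w_k = 1$ for main roads and `side_increment_factor` for side streets;
the maximum (rather than a sum) prevents double-counting at junctions. Each
emulated model is this one field averaged over its own cell size (on a
shared 5 m quadrature lattice, so a 100 m cell is *exactly* the mean of its
nested 25/50 m cells), plus an optional configured additive bias. Resolution
and bias are therefore the only inter-model differences, and every
cross-model statistic has a known expectation.

The street network is a jittered grid of blocks: regular enough to be a
plausible urban plan, irregular enough that equal-length route ties are
rare. Each street line is drawn as a side street with probability `p_side`.

**What the generator does not emulate** — and hence what a green test does
not establish: real geography and geocoding error, traffic counts and
meteorology, dispersion physics (street canyons, building effects),
route-choice behaviour (commuters deviating from shortest paths),
seasonality and weekends, and in-vehicle infiltration (deliberately out of
scope; ambient-level exposure is the target quantity). The pipeline's
correctness claims are algorithmic: the overlay, adjustment, aggregation
and comparison machinery is verified against independent oracles, not
against field measurements.

## 3. Why side streets get a smaller increment

With a single increment on every road, a paradox appears: commuter routes
lie *on* roads, so at 25 m resolution every route sees nearly the same
kerbside value and between-subject variance is *smaller* than at 100 m —
the opposite of the motivating observation that high-resolution models show
more within-city variability. That observation is driven by the contrast
between busy main roads and quiet side streets, which a fine raster
resolves and a coarse one averages away. The generator therefore scales the
side-street increment by `side_increment_factor` (default 0.5). With an
all-main network (or factor 1) the field reduces to the single-increment
form. This was fixed once, on mechanistic grounds; the cross-resolution
variance ordering is then a property of the stated world, verified in the
acceptance suite at n = 258.

## 4. Numerical and procedural choices

* **Routing ties**: among equal-length shortest paths the lexicographically
  smallest node-id sequence wins (tolerance 10⁻⁹), making routes — and the
  whole pipeline — deterministic. Dijkstra is hand-rolled because no
  off-the-shelf routine exposes this tie-break; an igraph cross-check runs
  in the unit tests.
* **Snapping**: origins/destinations snap to the nearest network node
  within 50 m; synthetic geocodes sit on nodes, so this guards only
  hand-built inputs.
* **Uneven trips**: a subject reporting an odd trip count gets the
  unmatched trip mirrored (geometry and leg order reversed, modes and
  durations kept), starting at the reported leave time for the opposite
  location. By default the generator emits complete 2/4-trip days (so
  distributional checks on trip counts apply directly); `uneven_fraction`
  produces incomplete diaries for exercising the completion rule.
* **Classification**: a leg's class is the class with the greatest
  overlapped length along the leg (arc-length slices ≤ 2 m attributed to
  the nearest segment within 5 m); ties go to main. Off-network legs use
  the total in-buffer (15 m) road length per class, again ties to main.
  Classification is invariant to vertex densification up to the slice
  resolution.
* **Ratios**: numerator and denominator both use weekdays only
  (`include_weekends` switches this); with equal hour-bin counts each ratio
  row averages to 1 by construction. One ratio per leg, fixed by the leg's
  start hour even if the leg spans an hour boundary.
* **Waits**: concentration is the point value of the containing cell;
  class is that of the nearest segment within 15 m, else side. Waits use
  ventilation ratio 1.0.
* **Cell indexing**: half-open lower-left-anchored cells; geometry touching
  the exact top/right raster boundary belongs to the last cell, so domain
  -filling networks never fall outside. A vertex outside the extent raises
  an error rather than being clamped.
* **Polynomial "best degree"**: lowest degree whose R² gain over the
  previous degree exceeds 0.01 (capped at n − 2). The rule is a package
  choice; only the chosen degrees, not the rule, appear in comparative
  reports.
* **Fisher–Pitman**: the variability comparison permutes pair members and
  uses $|SD(a) - SD(b)|$ with Monte-Carlo p
  $(1 + \#\{perm \ge obs\})/(1 + n_{perm})$; the statistic is a pluggable
  argument because the canonical form for spread comparisons is
  under-determined.
* **Difference orientation**: `bland_altman(a, b)` reports $b - a$;
  both orientations of any model pair are obtainable by argument order and
  the antisymmetry is tested, since published difference tables are not
  always sign-consistent.
* **Determinism**: one scenario seed derives independent sub-seeds per
  generator stage; two pipeline runs with the same seed produce
  byte-identical outputs (hash-verified). All clock times are minutes since
  midnight with no DST handling — negligible for annual means.

## 5. File formats

Rasters are ESRI ASCII grids (NODATA −9999) — diffable text with a
zero-dependency parser; networks and legs are GeoJSON LineString/Point
features in planar metres (no geographic CRS is emulated); populations,
station series, ratios, exposures and comparisons are CSV with a
seed-stamped comment header; the run manifest is JSON with md5 hashes of
every output.

## 6. Known limitations

* Pure-R geometry and routing: fine for networks of hundreds of nodes and
  populations of hundreds of subjects (the design scale); city-scale
  networks would want spatial indexing and compiled shortest paths.
* The buffer rule integrates in-buffer length by 0.5 m discretisation of
  road segments; pathological geometries near the buffer edge resolve at
  that resolution.
* Station series have no seasonality or autocorrelation; ratio-recovery
  tolerances are calibrated for iid noise.
* The synthetic world has exactly two road classes and one latent field;
  conclusions about real multi-model disagreement (different physics,
  different inputs) are out of reach by design — the configured additive
  `model_bias` is the only mechanism for structural disagreement.
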