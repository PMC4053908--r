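# no2commute

Population-based simulation of commuter exposure to nitrogen dioxide (NO2).

## The problem

Epidemiological studies of long-term air pollution effects usually assign
exposure at the home address only, ignoring the commute — the daily time
window spent closest to traffic, typically during rush hours when
concentrations peak. Estimating in-transit exposure for a whole population
requires geocoded travel diaries, a routable road network, one or more
annual-mean pollution surfaces, and temporal adjustment for the diurnal NO2
cycle. A practical question follows: does an expensive high-resolution
dispersion surface (25 m) change the population exposure estimates relative
to a coarse national model (100 m), or do the models merely differ in
small-scale variability?

`no2commute` implements that assessment pipeline end to end, exercisable
entirely on synthetic data with known ground truth:

1. **synthetic scenario** — a latent annual-mean NO2 field (suburban
   background + road-proximity increment decaying as `exp(-d/λ)`, larger on
   main roads than side streets), averaged onto rasters of 25/50/100 m so
   resolution is the only structural difference between the emulated models;
   a jittered street-grid network with main/side classes; a commuter
   population with multi-leg trips, rush-hour start times and waiting
   episodes; 30-min NO2 series for a street and a background monitoring
   station.
2. **routing** — deterministic shortest-by-distance routes (lexicographic
   tie-break), duplication of uneven trip counts, study inclusion filters.
3. **road classification** — main vs side street per leg by longest
   overlapped length, with a 15 m buffer rule for off-network legs.
4. **temporal adjustment** — hour-of-day factors `ratio_m[h]`, `ratio_s[h]`:
   annual weekday hourly mean / annual weekday mean at each station.
5. **exposure engine** — the core statistic per leg,
   `C_leg = Σ_cells C_grid · len_cell / Σ_cells len_cell`
   (exact polyline-in-cell lengths), then per subject
   `E_subject = Σ (C_leg · ratio · t_leg) + Σ (C_wait · ratio · t_wait)` and
   time-weighted exposure `E_subject / Σ t` (µg m⁻³), plus inhaled dose via
   ventilation ratios (walking 1.7, bicycle 2.0, motorized/public 1.0).
6. **model comparison** — Table-style summaries, Bland–Altman limits of
   agreement (mean ± 2 SD of paired differences), Spearman rank correlation,
   polynomial relation fits, Wilcoxon signed-rank test, and a Fisher–Pitman
   permutation test of spread differences.

## Worked example

```r
library(no2commute)

cfg  <- scenario_config(n_subjects = 40, seed = 1)
net  <- generate_network(cfg)
grids <- generate_rasters(cfg, net)           # model_25m / 50m / 100m
pop  <- classify_population(generate_population(cfg, net), net)
st   <- generate_station_series(cfg)
rt   <- compute_hourly_ratios(st$street, st$background)

expo <- compute_exposure(pop, rt, grids)
for (m in names(grids)) {
  s <- summarize_distribution(expo$time_weighted[expo$model_name == m])
  cat(sprintf("%-10s n=%d mean=%.1f sd=%.1f min=%.1f median=%.1f max=%.1f\n",
              m, s$n, s$mean, s$sd, s$min, s$median, s$max))
}
#> model_25m  n=40 mean=54.0 sd=9.6 min=40.4 median=53.1 max=71.9
#> model_50m  n=40 mean=52.0 sd=8.7 min=39.2 median=51.1 max=67.1
#> model_100m n=40 mean=47.7 sd=6.8 min=37.6 median=46.9 max=61.0

compare_models(expo, n_perm = 999, seed = 1)
#>     model_a    model_b mean_diff sd_diff spearman_rho fit_degree wilcoxon_p fisher_pitman_p
#> 1 model_25m  model_50m     -2.00    1.26        0.994          1   3.71e-08           0.046
#> 2 model_25m model_100m     -6.27    3.27        0.975          1   3.71e-08           0.018
#> 3 model_50m model_100m     -4.26    2.19        0.987          1   3.71e-08           0.016
```

Reading the output: the three rasters share one latent field, so
per-subject estimates are almost perfectly rank-correlated (Spearman
0.97–0.99) and mean time-weighted exposures agree within a few µg m⁻³, but
the finer rasters preserve the kerbside increment along routes (higher mean)
and the main/side street contrast (higher SD: 9.6 at 25 m vs 6.8 at 100 m) —
the Fisher–Pitman test flags exactly that spread difference (p ≈ 0.02–0.05)
while cell averaging at 100 m smooths it away. The hour-8 temporal factors
recovered from the stations (main 1.37, side 1.21) reflect the stronger
rush-hour peak at the street site.

The whole pipeline, file formats included (ESRI ASCII grids, GeoJSON legs,
CSV tables, JSON manifest):

```r
run_pipeline(pipeline_config(scenario_config(n_subjects = 25, seed = 1),
                             out_dir = "my_run"))
```

or from the shell:

```sh
Rscript inst/cli/commute-exposure.R demo --out my_run --seed 1
Rscript inst/cli/commute-exposure.R run --config pipeline.yaml
```

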