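# stableuse

Area and resource utilization of group-housed horses from GPS trajectories.

Horses in "active stable" group housing move freely between spatially
separated functional areas — feed stalls, lying halls, straw racks,
shelters, troughs, paddock and (seasonally) pasture. Given GPS collar
logs at one fix per 10 s, this package quantifies how the herd uses that
space: which areas are occupied, how much of the farm each horse covers
per hour, and which horse-, day- and resource-level factors drive it. It
is written for researchers in equine behaviour / precision livestock
farming who have per-animal logger CSVs and a farm plan, and for method
work on such pipelines via its built-in herd simulator.

## Method

The farm is projected to local planar metres and divided into a grid of
3 × 3 m squares. Raw fix streams pass a cleaning cascade: fixes outside
the farm's bounding box are dropped, then fixes implying speeds > 50 km/h
or steps > 140 m per 10 s (recomputed geodesically, with a sequential
anchor so one spike cannot cascade), then fixes outside the paddock and
pasture polygons. Two responses are computed, each with a "with pasture"
and a "paddock only" variant and a 12 h day-inclusion rule (≥ 4320 fixes
per horse-day):

* **Squares per hour** — for each horse-day, the number of distinct
  squares visited per clock hour, averaged over well-covered hours.
  Modelled as

  `y_ijkl = mu + B_i + S_j + D_k + A_l(B_i) + b * age_ijkl + e_ijkl`

  with fixed breed `B`, sex `S`, observation day `D`, age covariate `b`,
  and a random animal intercept `A` nested in breed (REML via lme4;
  AICc/BIC forward selection of fixed effects on ML fits; least-square
  means with Bonferroni-corrected pairwise comparisons via emmeans).

* **Square usage frequency** — per square and day, the percentage of
  that day's fixes (all horses) in the square, modelled as
  `y_ijk = mu + D_i + L_j + e_ijk` with day `D` and resource location `L`
  (feed stalls FS_1–7, concentrate stalls CF_1–3, lying halls LH_1–3,
  straw racks RF_1–2, shelters SH_1–2, troughs TR_1–2, paddock, pasture),
  plus seasonal occupancy heatmaps.

Because raw farm datasets of this kind are typically not deposited, the
package includes a behavioural-state herd simulator (semi-Markov dwell /
travel states with resource attraction, summer pasture windows, GPS
noise, teleport spikes, dropouts) whose ground truth (per-horse mobility
effects, age slope, injected spikes) makes every downstream stage
testable by parameter recovery.

## Worked example

```r
library(stableuse)

layout <- example_layout(n_days = 10, summer_days = 10)
grid   <- grid_for_layout(layout)            # 3 m cells over the farm
metas  <- horse_metas(16, n_newcomers = 0, n_days = 10, seed = 1)
cfg    <- sim_config(n_horses = 16, n_days = 10, summer_days = 10,
                     spike_prob = 0.001, rng_seed = 1)
study  <- simulate_study(metas, layout, cfg, days = 1:5)

cleaned <- filter_fixes(study$fixes, layout)
cleaned$report
#>          input   outside_bbox speed_distance  outside_areas       retained
#>         677335            648             42           4288         672357

usage <- horse_day_usage(cleaned$fixes, layout, grid)
mean(usage$squares_per_hour[usage$included])
#> [1] 48.6

fit <- fit_model1(usage, metas)
fit
#> <model1_fit> squares/h ~ breed + sex + day + age + (1|animal)
#>   n = 80 horse-days, sigma_a2 = 144.64, sigma_e2 = 33.06
#>   age slope b = -0.736 +/- 0.498 (p = 0.167)
#>   AICc = 539.8, BIC = 562.1

freqs <- square_frequencies(cleaned$fixes, grid, layout)
head(location_usage(freqs), 3)
#> # A tibble: 3 x 3
#>   location n_square_days mean_frequency
#> 1 FS_1                20          0.256
#> 2 FS_2                20          0.329
#> 3 FS_3                20          0.297
```

The filter report shows the cascade's accounting (removed + retained =
input). The five-day, 16-horse toy herd covers ~49 distinct squares per
hour; the fitted age slope is negative (each extra year of age costs
about 0.7 squares/h here), and the animal variance component dominates
the residual, i.e. horses differ far more from each other than a horse
does from day to day. Location usage is the mean per-square daily
frequency for each resource: feed stalls are visited an order of
magnitude above the per-square average, as on a real farm. A seasonal
heatmap comes from `seasonal_heat_grid()` + `render_heatmap()`.

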