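---
title: "Quantifying area and resource use of group-housed horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying area and resource use of group-housed horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures implemented in
`stableuse`, the assumptions behind them, the choices made where the
design was genuinely open, and what the package's synthetic-data tests do
and do not establish about real logger data.

## The measurement model

A GPS collar at 0.1 Hz yields a fix stream per horse: local and UTC
timestamp, latitude/longitude, height, device speed and step distance.
The analysis lives on a 3 × 3 m grid over the farm — roughly a horse
length, and compatible with the 3 m proximity threshold commonly used for
contact definitions between collared horses. All geometry is done in a
local planar frame.

**Projection.** Farm extents here are a few hundred metres, so a local
equirectangular projection about the farm centroid suffices: east
`x = N(phi0) cos(phi0) dlon`, north `y = M(phi0) dlat`, with `M` and `N`
the WGS84 meridional and prime-vertical radii of curvature at the origin
latitude. Using the two curvature radii (rather than a single mean Earth
radius) keeps planar distances within 0.005% of geodesic distances at
1 km — an order of magnitude tighter than the 0.05% the pipeline's tests
require — at no extra cost. The inverse is exact, and `geosphere`'s
geodesics serve as the independent oracle in the test suite.

**Grid.** The grid anchors at the south-west corner of the farm's planar
extent with east/north axes; cells are half-open intervals
`[k s, (k+1) s)` so that edge points belong to the higher-index cell and
square assignment is a total function. Squares inherit the label of the
resource zone containing their centre; centre containment (instead of
area overlap) is deterministic, fast, and differs from overlap weighting
only for the sliver of cells straddling a zone boundary — a sensitivity
worth keeping in mind when interpreting per-resource numbers, since a
3 m cell adjacent to a feed stall can capture queueing horses either way.

## Filtering

The cleaning cascade runs in a fixed order: geodetic bounding box, then
speed/step-distance, then paddock/pasture clipping. The order matters
only for attribution in the filter report (each rule sees what the
previous retained); the retained set is checked idempotent. Thresholds
default to 50 km/h and 140 m per 10 s — generous bounds on equine
locomotion — and the step allowance scales proportionally across gaps
(140 m per 10 s of elapsed time). Step distances are recomputed from
coordinates rather than trusted from the device column so that filtering
and gridding stay consistent; the device column is retained for audit.
Removal is sequential with an anchor at the last retained fix, so a
single teleported fix is removed without cascading removals of the valid
fixes after it. Horse-days whose removed or malformed fraction exceeds
20% can be excluded wholesale (`flag_damaged_days()`), the
operationalisation of "damaged or mis-adjusted logger" exclusions.

## Responses and inclusion rules

**Squares per hour.** For each horse-day, each clock hour with at least
90% of its expected fixes (324 of 360) contributes the count of distinct
squares among its fixes; the response is the mean over qualifying hours.
A square revisited in two different hours counts in each hour — the
statistic measures hourly spatial coverage, not daily range. The
alternative reading (distinct squares per day divided by hours recorded)
is not offered because it conflates coverage with recording length. The
90% hour-coverage rule keeps sparsely recorded hours from biasing the
mean; the day itself enters the model only with at least 12 h of data,
i.e. `n_fixes >= 4320` at 10 s sampling, with the boundary inclusive.
Both rules are applied per dataset variant — removing pasture fixes can
push a day below 12 h, so the paddock-only dataset is smaller.

**Usage frequency.** Per square and day, 100 × (fixes in square) /
(fixes that day, all horses). Frequencies over a day sum to 100% by
construction (asserted to 1e-9 relative in tests). Only visited
(square, day) rows are materialised and modelled; never-visited squares
count toward the visited-universe size but contribute no rows — matching
how visited-square universes are reported for such data. Zero-filling
all squares would shift location means toward zero in proportion to zone
area, which is a different (and defensible) estimand, but not the one
used here.

## The two models

Model 1 is a linear mixed model for squares per hour:
`y ~ breed + sex + day + age + (1 | animal)`, day as a factor, the
animal intercept random and nested in breed by construction (each animal
has one breed). Final inference uses REML; AICc/BIC forward selection of
fixed effects uses ML fits, because likelihoods of REML fits with
different fixed-effect structures are not comparable. AICc is
`AIC + 2k(k+1)/(n-k-1)` with `k` counting all parameters including
variance components, and a candidate is refused outright when
`n <= k+1`. Least-square means use equal factor-level weights with age
at its observed mean (the SAS LSMEANS convention); pairwise LSM
differences are Bonferroni-corrected by the number of pairs with
significance at p < 0.05. Degrees of freedom for LSM tests default to
asymptotic z; Satterthwaite is available behind `df_method =
"satterthwaite"` where small-sample accuracy matters more than speed.
Per-animal effects are BLUPs from the REML fit.

Model 2 is a two-way fixed-effects model for square-day frequency:
`y ~ day + location`, ordinary least squares on the visited rows.
Location LSMs summarise resource usage the way a per-resource average of
assigned squares does. Residuals of the with-pasture variant are heavily
leptokurtic — a large pasture contributes thousands of near-zero
frequencies against a few large resource squares — and excess kurtosis
drops substantially when pasture is excluded; the package reports the
kurtosis rather than transforming the response, keeping the two variants
comparable.

## The herd simulator

Because farm GPS datasets of this kind are generally not deposited, the
simulator is a first-class module, built to emulate the statistical
structure of a 52-horse, 227-day study: a 159-day summer with twice-daily
~90 min pasture windows and a 68-day winter; 31/6/15
warmblood/pony/other breed classes; geldings and mares; ages 2–29; 12
newcomers entering after day 1.

Movement is a semi-Markov behavioural state machine: the horse
alternately walks to a target (lying hall, feed or concentrate stall,
trough, straw rack/shelter, a random paddock spot, or open pasture
during a window) and dwells there for an exponential time, with
small-scale wander while dwelling and lateral jitter while walking.
Travel between paddock and pasture routes through the pasture gate so
noiseless trajectories stay inside the fences. The observation process
adds isotropic Gaussian GPS noise (default 1.5 m), teleport spikes of
160–500 m with configurable probability (to exercise the filters), and
fix dropouts.

Per-horse mobility is monotone in a score
`mobility_base + age_slope (age - age_ref) + animal_effect`, with the
age slope defaulting to −0.6 per year and the animal effect drawn once
per horse from N(0, `animal_sd`²), `animal_sd` defaulting to 8 — chosen
to mirror a per-animal spread of roughly ±18 squares/h across a herd.
The score acts on the behavioural switch rate, never directly on the
response, so recovery tests stay honest: the response effect must emerge
from behaviour. The switch rate is `(score/base)^gamma` with
`mobility_gamma = 1.8`, calibrated once so that one unit of score moves
the realised response by about one distinct square per hour — that
calibration is what entitles the config to document `age_slope` and
`animal_sd` in squares/h units (the raw switch rate alone
under-transmits, because travel time and dwell spread also shape the
hourly count). With the default geometry the baseline horse realises
about 52 distinct squares/h, with per-day SDs around 10.

Seeding is by counter: every horse-day (and each horse's animal effect)
derives its own substream from the root seed, so any subset of horses or
days reproduces byte-identically.

What the simulator does *not* emulate: social structure (dominance,
cohesion, contact networks), GPS multipath or canyon effects near roofs,
battery-driven logger swaps, or empirically grounded diurnal rhythms —
the within-day activity profile is a free modelling choice. Passing
recovery tests therefore demonstrate that the pipeline's estimators
invert the pipeline's own generative assumptions at realistic noise
levels, not that they are robust to every pathology of field data.

## Numerical and degenerate-input choices

* Half-open grid cells; edge points go to the higher-index cell.
* A horse-day with enough fixes but no hour reaching 90% coverage has an
  undefined response and is dropped with its reason, not imputed.
* Empty location levels are dropped from model 2 with a warning;
  locations with no squares are absent from usage summaries, not zero.
* Variance components are REML-estimated and non-negative by
  construction (lme4's parameterisation); a singular design (one sex
  observed, a breed with fewer than two animals) is refused with the
  aliased term named rather than silently dropped.
* An all-zero heat grid renders with an annotation instead of erroring,
  and rendering writes the matrix alongside the image so the plotted
  data is auditable.

## Problem sizes used in the test suite

The packaged tests run the oracle-equivalence checks at 10⁴ random
points, the filter-recovery check at 5 horses × 3 days with spike
probability 0.001, and the parameter-recovery experiment at 10
replicates of 20 horses × 60 days (a proportional 42/18 summer/winter
split) — the scale at which the mixed model recovers the configured age
slope's sign in all replicates and the pooled BLUP–truth Spearman
correlation exceeds 0.8, while keeping the whole suite to a few minutes.
Larger studies (the full 52 × 227) run with the same code and scale
linearly in horse-days.

## Known limitations

* The square-to-resource assignment by cell centre undercounts zones
  smaller than a cell (a 2 × 2 m trough may own no square); enlarging
  zone polygons by a margin is the practical workaround.
* The paddock-only variant recomputes frequencies over paddock fixes
  only; comparing its percentages with the with-pasture variant compares
  shares of different denominators, which is intended (shares of time on
  the reduced area) but easy to misread.
* The simulator's rectangular-region assumption (clamping to polygon
  bounding boxes) is exact for the shipped layouts; strongly non-convex
  farm polygons would need a richer routing model.
* Bonferroni over all day pairs (227 levels gives 25,651 comparisons) is
  conservative; the package reports it as specified rather than
  switching to less conservative families.
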