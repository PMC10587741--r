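---
title: "Methods: clustering diurnal stem cycles and projecting intra-annual growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering diurnal stem cycles and projecting intra-annual growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `intragro`, the
assumptions it makes, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices taken where the design was genuinely open.

## The model in one paragraph

Stem circumference measured every 30 minutes mixes reversible water-driven
swelling/shrinkage with irreversible growth. Rather than decomposing the
two physically, the pipeline treats each day's 48-point cycle as a shape,
clusters the shapes, and lets the clusters act as weather-indexed growth
states: clusters whose member days end above where they started are
"growing" (GC), the rest "non-growing" (NGC). Daily weather predicts the
day's cluster well, so a classifier trained on the observed period can
label future days from downscaled climate-model output, and a linear model
from monthly GC-day counts to monthly circumference change (GRO, the sum of
daily morning-maximum differences) converts those labels into projected
growth. Season timing comes from a smooth of cumulative growth over day of
year: onset and cessation are the days the curve crosses 2.5% and 97.5% of
its annual total.

## Preprocessing

* **Grid**: readings are snapped to a regular 30-min grid; timestamps are
  treated as timezone-naive local time.
* **Gap filling**: gaps up to 24 h are interpolated with a cubic spline
  through up to 24 h of flanking readings on each side (an interpolating
  cubic reproduces locally smooth, quadratic-like courses exactly). Longer
  gaps use peer trees: each peer covering the gap is z-standardized over a
  ±3-day window of the target's available readings, the standardized
  courses are averaged, and the average is mapped back through the
  target's window mean and SD. The z-scoring makes the fill invariant to
  inter-tree level offsets; a long gap with no covering peer is an error,
  never silently interpolated.
* **Jump removal**: any 30-min step larger than 1.0 mm (configurable) is
  treated as a band re-adjustment or battery artefact and subtracted from
  all subsequent readings. The whole step is removed, so the natural
  sub-step change at the jump reading (≪ 0.1 mm) is lost with it — the
  cost of not modelling the artefact's exact onset.
* **Morning maximum and DCC**: the morning window is 00:00–11:59; diurnal
  cycles peak before noon, so the pre-noon maximum is the day's hydrated
  reference state. DCC(d) = morning_max(d+1) − morning_max(d), attributed
  to day d, whose weather and cluster label it shares. Days with no
  pre-noon reading are flagged missing and excluded from clustering and
  monthly sums — never imputed as zero. DCC telescopes exactly: its sum
  over any span equals the difference of the bounding morning maxima.

## Cycle clustering

Rows are zero-anchored (the day's first reading is subtracted): absolute
circumference differs across trees and years by tens of millimetres and
would swamp shape. Distances are classic dynamic time warping with
symmetric steps, squared-Euclidean local cost and no warping window (a
Sakoe–Chiba band would be a natural restriction but none is imposed, since
48-point days are short); the reported value is the square root of the
accumulated cost. Centroids are DTW barycenter averages (DBA), capped at
10 inner iterations with a 1e-6 movement tolerance.

k-means uses seeded k-means++ initialization (new centroids sampled with
probability proportional to the squared DTW distance to the nearest chosen
centroid). Plain random-row initialization was observed to land in a local
optimum that splits the dominant winter cluster while merging the two
small growing clusters; k-means++ seeds small, well-separated clusters
reliably, and the correct partition also has the lower inertia, so this is
an optimization aid, not a change of objective. The objective and the
reported inertia are the sum of DTW distances of rows to their assigned
centroid; the best of `n_init = 5` restarts is kept, and a restart stops
when labels stabilise or the inertia improves by less than 1e-4
relatively.

**Elbow rule.** The scan fits each candidate k (default 2–8) with lighter
effort (`n_init = 2`, `dba_iter = 5`) plus *incremental seeding*: the
previous k's centroids, augmented by the row they fit worst, are tried as
one extra start. This keeps the inertia curve close to the optimal
envelope — a single failed scan optimum can otherwise distort the curve
enough to move the pick. The pick itself normalizes both axes to [0, 1]
and takes the k farthest below the chord joining the endpoints, with ties
broken toward smaller k. Two degenerate shapes have no elbow and fall back
to the smallest candidate with a warning: a flat curve (total relative
drop below 15% — the structure is already resolved at the smallest k) and
an essentially linear decay (no point further than 0.02 normalized units
from the chord).

**Groups.** A cluster is growing when its mean net daily change exceeds
0.005 mm. The tolerance encodes measurement resolution: a cluster of truly
stable days has an empirical mean net change of ± sampling noise, and a
strict sign test would classify it by a coin flip; 0.005 mm/day is far
below any daily increment a band dendrometer resolves as growth and far
below the smallest growing archetype (0.03 mm/day).

**Cluster–weather tests.** Kruskal–Wallis per climate variable, then
Dunn's pairwise rank z tests with the usual tie correction and Bonferroni
adjustment (the adjustment is a design choice; the method itself does not
fix one). The compact letter display assigns one letter per maximal clique
of the non-significance graph, computed exhaustively (k ≤ 12).

## Climate derivations

Potential evapotranspiration uses the Hargreaves–Samani form
PET = 0.0023 · Ra · (Tmean + 17.8) · √(Tmax − Tmin) with the FAO-56
extraterrestrial radiation Ra (converted at 0.408 mm per MJ m⁻²) and
results clipped at zero; the constants are the canonical published set.
The moisture index is precipitation − PET. Dry spells are maximal runs of
days below a 0.1 mm trace threshold (configurable; the choice of trace
threshold can move spell lengths on real data). Site latitude is a
configuration input.

## Climate-model evaluation and downscaling

Candidates are scored per variable by the Kling–Gupta efficiency on
monthly series over the common calibration months and ranked by the
unweighted mean of the three scores; variables at or below KGE 0.5 are
flagged as poor skill. Daily downscaling is a 500-tree random forest per
temperature variable and the two-step forest for precipitation (wet/dry
classification, then amounts regressed on observed-wet days only;
predicted-dry days are exactly zero and amounts are clipped nonnegative).
Besides the simulated value, both downscalers use two day-of-year harmonic
pairs as covariates (`covariates = "sim-only"` disables them): the
mapping between model and station values is seasonally varying, and the
forest cannot discover season from a single daily value. Forests are
seeded and single-threaded, so every run is reproducible.

## Growth model and projection

The headline model regresses site-mean monthly GRO on the stacked monthly
GC-day count by ordinary least squares; per-cluster and NGC variants run
through the same interface. Validation is 10-fold *blocked* CV: months stay
in time order, are cut into 10 contiguous blocks (remainder months spread
one per block from the first), and each fold holds one block out. R² is
1 − SS_res/SS_tot and variance explained 1 − var(resid)/var(obs), both on
the held-out block, matching the conventions of the machine-learning
toolkits this kind of pipeline is usually built with; both equal 1 on
noiseless data, and R² can be strongly negative on short, low-variance
blocks (e.g. winter months where both growth and counts are near zero) —
a property of blocked CV on seasonal data, not a numerical fault.

Projections average each scenario window's monthly GC counts by calendar
month, predict GRO, and express changes against the observed-period
monthly means: per-month percent change 100·(pred − obs)/obs (undefined
and flagged where the observed mean is zero) and a total change weighted
by observed monthly growth, which equals the percent change of the annual
sum. Season-shift aggregation across scenarios reports mean ± population
(n-divisor) standard deviation, rounded to whole days — the population
convention is what the reported spreads of this kind of scenario table
require, since the scenarios are the whole set under study, not a sample.

## Phenology

Cumulative growth is smoothed with a penalized cubic regression spline
(`mgcv::gam`, basis dimension 12 by default, shrunk to n − 2 when few
points are supplied) and the daily rate is the derivative of the smooth,
evaluated by centred finite differences of the linear-predictor matrix
(step 1e-3 days) — the standard mgcv construction, exact for the spline
basis up to the difference step. The smooth is not forced monotone;
non-monotonicity is recorded on the object. Onset/cessation thresholds
(2.5%/97.5%) are relative, so season dates are invariant to rescaling.

Observed-period curves accumulate the cross-tree mean DCC per day of year
(Feb 29 merged into DOY 60). Future curves need a daily disaggregation
that the monthly projection does not define; the package places the
window-averaged predicted monthly GRO as cumulative points at month-end
DOYs with a zero anchor at DOY 1 and smooths those 13 points. This choice
is isolated in `future_cumulative_points()`; any other disaggregation can
be substituted there. Because the linear growth model predicts winter
months from a near-zero GC count plus a (often negative) intercept, future
curves can start flat or dipping and the projected onset can move by far
more days than the underlying climate shift — season deltas should be read
with the model structure in mind.

## The synthetic world

The generator emulates the statistical structure the pipeline assumes, not
tree physiology:

* **Climate**: sinusoidal Tmax (annual mean 26 °C, amplitude 5.5 °C,
  June peak) with a seasonally varying diurnal range; wet-day occurrence
  and gamma-distributed amounts peak in August, and monsoon-month amounts
  are rescaled in closed form so the *expected* June–September share of
  annual precipitation equals 78%. Rain cools Tmax by 2.5 °C, creating
  the wet-cool class.
* **Cycles**: four archetypal 48-point shapes with net daily changes
  +0.08, +0.03, 0.00 and −0.04 mm — two growing, one stable, one
  shrinking. A deterministic rule assigns each day's archetype from
  realized weather (wet ≥ 1 mm; warm ≥ 29 °C on Tmax); days are the
  archetype plus N(0, 0.01 mm) noise, chained so each day starts where the
  previous ended. Shapes were chosen once so that all pairwise DTW
  distances are large against the noise floor; the default world yields
  roughly 64/14/18/4% frequencies for the stable, wet-cool, warm-dry and
  wet-warm classes.
* **Artefacts**: ±5 mm jumps at fixed interior fractions of the record and
  6 h/48 h gaps staggered across trees (so peers always cover long gaps),
  all positioned away from each other to keep the artefacts separable and
  recorded in the truth tables.
* **Climate model**: station series plus additive temperature bias
  (+1.5 °C, noise SD 0.8) and multiplicative precipitation bias (×1.15)
  with wet-day thinning (85% kept) and occasional false wet days; scenario
  series to 2100 recycle the observed climatology with linear warming of
  1.2/2.0/3.0/4.2 °C and precipitation factors 0.97/0.93/0.88/0.82 by 2100
  for the four pathways, then receive the same model bias.
* **Truth**: daily archetype labels, jump/gap positions, the noise-free
  monthly growth table, and a construction-truth slope. Because the two
  growing archetypes have different net changes, no single planted scalar
  slope exists a priori; the truth slope is defined as the OLS slope of
  the noise-free monthly growth on the true GC-day counts, which is the
  quantity the pipeline's estimate should recover.

What passing tests on this world show — and do not show: recovery of
planted structure demonstrates that each algorithm does what it claims
under the stated noise model (independent Gaussian cycle noise, exact
weather rule, stationary archetypes). Real dendrometer data add
autocorrelated hydraulic noise, drifting cycle shapes, bark artefacts and
non-deterministic weather dependence; performance numbers from the
synthetic world do not transfer to real data, only the correctness of the
mechanics does.

## Problem sizes and determinism

The default study conditions are five years and four trees (~7,300
stacked tree-days); unit tests use one-year/two-tree worlds. A full
pipeline run — elbow scan over k = 2–8, final clustering, classifier,
four-scenario downscaling to 2100, projection and phenology — takes about
two minutes on one CPU. Every stochastic step (generator, k-means
restarts, forest fits, splits) derives its seed from the run's master
seed, and reruns are bit-identical; forests run single-threaded for this
reason.

## Known limitations

* GC/NGC and the growth model treat all growing days as exchangeable up to
  the count; sub-daily phase decomposition and water-storage separation
  are out of scope.
* The linear count-to-growth model extrapolates poorly into winters (see
  the intercept remark above) and carries no uncertainty from the
  classifier into the projections.
* Downscaling corrects marginal distributions conditionally on the
  simulated value and season; it cannot add skill the climate model lacks,
  and no quantile-mapping variant is provided.
* The elbow method needs the true k strictly inside the scanned range to
  produce a chord elbow; at the boundary it relies on the flat-curve
  fallback.
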