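# intragro

Intra-annual tree growth projection from dendrometer cycle clustering.

Band dendrometers record stem circumference every 30 minutes. Each day
traces a characteristic diurnal cycle — nighttime rehydration and growth,
daytime transpiration-driven shrinkage — whose shape depends on the day's
weather. `intragro` turns a few years of such records plus daily station
climate into a projection of monthly growth and growing-season timing under
future climate scenarios:

1. **Preprocess** — fill gaps (cubic spline up to 24 h, peer-network
   interpolation beyond), remove sensor jumps, and reduce each day to its
   morning maximum; the difference of consecutive morning maxima is the
   daily circumference change (DCC), the daily growth proxy.
2. **Cluster** — stack every complete tree-day as a zero-anchored 48-point
   row and cluster the cycles with k-means under dynamic time warping
   (DTW), with DTW barycenter averaging for the centroids; choose k by the
   elbow method; clusters with positive mean net change form the growing
   group (GC), the rest the non-growing group (NGC); Kruskal–Wallis plus
   Dunn post-hoc tests characterise each cluster's weather.
3. **Classify** — a random forest maps daily Tmin, Tmax, precipitation and
   calendar month to the day's cycle cluster (stratified 60/40 split,
   precision/recall/F1 report with F1 = tp / (tp + (fp + fn)/2)).
4. **Downscale** — candidate climate-model series are ranked by the
   Kling–Gupta efficiency, KGE = 1 − √((r−1)² + (β−1)² + (γ−1)²); daily
   temperature is corrected by random-forest regression and precipitation
   by the two-step forest (wet/dry classification, then amounts on wet
   days).
5. **Project** — the classifier labels every future day; monthly GC-day
   counts drive an ordinary least-squares growth model
   GRO = a + b · GC-days (validated by 10-fold blocked cross-validation);
   a penalized-spline smooth (GAM) of cumulative growth yields the daily
   growth rate and the statistical season onset/cessation, the days the
   curve crosses 2.5% / 97.5% of its annual total.

A seeded synthetic-data module generates the whole input world — monsoonal
climate, four archetypal diurnal cycles driven by a deterministic weather
rule, sensor jumps and gaps, biased climate-model output — with ground
truth attached, so every stage is testable without field data.

## Worked example

```r
library(intragro)
res <- run_pipeline(seed = 1, years = 5, n_trees = 4, k = "auto",
                    verbose = FALSE)

res$elbow_k
#> [1] 4
#> attr(,"k_range") 2 3 4 5 6 7 8
#> attr(,"inertia") 586.4 415.8 339.3 325.8 325.6 321.2 320.4

res$groups
#>   cluster    n net_change_mm group
#> 1       0 4568 -0.0001483576   NGC
#> 2       1 1316 -0.0400661842   NGC
#> 3       2  253  0.0296935061    GC
#> 4       3 1171  0.0799078149    GC

res$growth_model
#> Linear growth model: GRO = -0.1475 + 0.0146 x GC-days (mm/month, n = 60)

res$obs_season
#> SOS = DOY 36, EOS = DOY 345, GS = 309 days
```

The elbow finds the four planted cycle archetypes; two clusters grow
(mean daily net change +0.080 and +0.030 mm) and two do not (−0.040 and
~0 mm). The growth model converts monthly growing-cluster days into
mm/month of circumference growth, and the cumulative-curve smooth places
the observed growing season between day-of-year 36 and 345. Per-scenario
season shifts are in `res$season_deltas` (positive = later/longer), and
`res$delta_stats` aggregates them as mean ± population SD per period.

A thin command-line front-end mirrors the two entry points:

```sh
exec/intragro simulate --seed 42 --years 5 --trees 4 --out-dir sim/
exec/intragro run --seed 42 --k auto --out-dir out/
```

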