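#' Define a synthetic study system
#'
#' Bundles every parameter of the seeded generator: four archetypal diurnal
#' circumference cycles (two growing, one stable, one shrinking; net daily
#' changes +0.08, +0.03, 0.00 and -0.04 mm), a deterministic weather rule
#' mapping daily temperature/precipitation classes to archetypes, a monsoonal
#' climate with a stated June-September precipitation share, sensor jump/gap
#' injection, and climate-model bias settings. Regenerating with the same
#' seed reproduces all outputs exactly, and ground truth (daily archetype
#' labels, jump positions, construction slope) is always emitted.
#'
#' @param seed integer seed.
#' @param years number of observation years (record starts 1 Jan
#'   `start_year`).
#' @param n_trees number of dendrometer trees.
#' @param start_year first observation year.
#' @param noise_sd per-point Gaussian noise on the diurnal cycles (mm).
#' @param monsoon_share target June-September share of annual precipitation.
#' @param wet_mm rain threshold of the weather rule (mm/day).
#' @param warm_c warm-day threshold of the weather rule (deg C, on Tmax).
#' @param jumps_per_tree artificial sensor jumps injected per tree.
#' @param gaps_per_tree short (6 h) and long (48 h) gaps injected per tree.
#' @param temp_bias,temp_noise_sd additive climate-model temperature bias and
#'   noise (deg C).
#' @param prec_bias multiplicative climate-model precipitation bias.
#' @param prec_keep probability a station wet day stays wet in the model.
#' @param prec_false_wet probability a station dry day is wet in the model.
#' @return object of class `synthetic_world`.
#' @export
synthetic_world <- function(seed = 42, years = 5, n_trees = 4,
                            start_year = 2016, noise_sd = 0.01,
                            monsoon_share = 0.78, wet_mm = 1, warm_c = 29,
                            jumps_per_tree = 2,
                            gaps_per_tree = c(short = 2, long = 1),
                            temp_bias = 1.5, temp_noise_sd = 0.8,
                            prec_bias = 1.15, prec_keep = 0.85,
                            prec_false_wet = 0.05) {
  stopifnot(years >= 1, n_trees >= 1)
  structure(list(
    seed = seed, years = years, n_trees = n_trees, start_year = start_year,
    noise_sd = noise_sd, monsoon_share = monsoon_share,
    wet_mm = wet_mm, warm_c = warm_c,
    jumps_per_tree = jumps_per_tree, gaps_per_tree = gaps_per_tree,
    temp_bias = temp_bias, temp_noise_sd = temp_noise_sd,
    prec_bias = prec_bias, prec_keep = prec_keep,
    prec_false_wet = prec_false_wet,
    archetypes = .make_archetypes(),
    nets = c(0.00, 0.08, -0.04, 0.03),  # archetype 0..3 net daily change, mm
    ssp_warming = c(ssp126 = 1.2, ssp245 = 2.0, ssp370 = 3.0, ssp585 = 4.2),
    ssp_prec_factor = c(ssp126 = 0.97, ssp245 = 0.93, ssp370 = 0.88,
                        ssp585 = 0.82)),
    class = "synthetic_world")
}

# Four archetype cycles (48 half-hourly offsets, first element 0), built
# from anchor points by monotone interpolation:
#   0: cold/dry  - small morning rise, back to zero (net 0.00)
#   1: wet/cool  - steady rise all day (net +0.08)
#   2: warm/dry  - morning rise, deep midday shrink (net -0.04)
#   3: wet/warm  - pronounced morning peak, midday dip, recovery (net +0.03)
.make_archetypes <- function() {
  h <- (0:47) / 2
  interp <- function(hk, vk) stats::spline(hk, vk, xout = h, method = "fmm")$y
  a0 <- interp(c(0, 4, 8, 12, 16, 20, 23.5),
               c(0, 0.02, 0.03, 0.012, 0.002, 0.0005, 0))
  a1 <- interp(c(0, 6, 12, 18, 23.5),
               c(0, 0.022, 0.042, 0.063, 0.08))
  a2c <- interp(c(0, 4, 7, 11, 15, 20, 23.5),
                c(0, 0.025, 0.04, -0.03, -0.10, -0.06, -0.04))
  a3c <- interp(c(0, 5, 9, 12, 15, 20, 23.5),
                c(0, 0.07, 0.14, 0.05, -0.02, 0.01, 0.03))
  m <- rbind(a0, a1, a2c, a3c)
  m[, 1] <- 0
  m[1, 48] <- 0.00; m[2, 48] <- 0.08; m[3, 48] <- -0.04; m[4, 48] <- 0.03
  rownames(m) <- paste0("archetype", 0:3)
  m
}

.world_dates <- function(world) {
  seq(as.Date(sprintf("%d-01-01", world$start_year)),
      as.Date(sprintf("%d-12-31", world$start_year + world$years - 1)),
      by = "day")
}

#' Generate the synthetic daily station climate
#'
#' Sinusoidal annual temperature course with a monsoonal precipitation
#' regime: wet-day probability and gamma-distributed amounts peak in
#' June-September, calibrated so that the expected June-September share of
#' annual precipitation equals the world's `monsoon_share`. Rain cools the
#' day (Tmax is reduced on wet days), which creates the wet/cool weather
#' class; tmax >= tmin is enforced by construction.
#'
#' @param world a [synthetic_world()].
#' @return data.frame `date`, `tmin_c`, `tmax_c`, `prec_mm`.
#' @export
gen_climate <- function(world) {
  set.seed(world$seed)
  dates <- .world_dates(world)
  doy <- as.POSIXlt(dates)$yday + 1
  n <- length(dates)
  # precipitation: seasonal wet probability and gamma amounts
  bump <- exp(-((doy - 213) / 58)^2)
  p_wet <- 0.06 + 0.78 * bump
  shape <- 0.9
  scale <- 2 + 14 * bump
  monsoon <- as.integer(format(dates, "%m")) %in% 6:9
  e_daily <- p_wet * shape * scale
  M <- sum(e_daily[monsoon]); O <- sum(e_daily[!monsoon])
  alpha <- world$monsoon_share * O / ((1 - world$monsoon_share) * M)
  scale[monsoon] <- scale[monsoon] * alpha
  wet <- stats::rbinom(n, 1, p_wet) == 1
  prec <- numeric(n)
  prec[wet] <- stats::rgamma(sum(wet), shape = shape, scale = scale[wet])
  # temperature: annual sine with pre-monsoon maximum, rain cooling
  tmax <- 26 + 5.5 * sin(2 * pi * (doy - 75) / 365) +
    stats::rnorm(n, sd = 1.3) - 2.5 * wet
  dtr <- 9 + 3 * cos(2 * pi * (doy - 10) / 365) +
    pmax(-2, stats::rnorm(n, sd = 0.8))
  tmin <- tmax - pmax(2, dtr)
  data.frame(date = dates, tmin_c = round(tmin, 2), tmax_c = round(tmax, 2),
             prec_mm = round(prec, 2))
}

# the deterministic weather -> archetype rule
.weather_archetype <- function(world, tmax, prec) {
  ifelse(prec >= world$wet_mm,
         ifelse(tmax >= world$warm_c, 3L, 1L),
         ifelse(tmax >= world$warm_c, 2L, 0L))
}

#' Generate dendrometer series with ground truth
#'
#' Each day's archetype is picked by the deterministic weather rule; the
#' day's 48-point cycle is the archetype plus Gaussian noise, chained so the
#' next day starts where the previous ended. Sensor jumps (+/- 5 mm level
#' shifts) and gaps (6 h and 48 h runs of missing readings, never at the
#' series ends and staggered across trees so peers always cover long gaps)
#' are injected per the world spec.
#'
#' @param world a [synthetic_world()].
#' @param climate a [gen_climate()] data.frame.
#' @return list: `series` (named list of raw per-tree data.frames with NA
#'   readings at gaps), `truth` (list with `labels` data.frame
#'   (tree_id, date, archetype), `jumps`, `gaps`, `monthly` construction
#'   table and `slope` = OLS slope of noise-free monthly growth on true
#'   GC-day counts).
#' @export
gen_dendrometer <- function(world, climate) {
  set.seed(world$seed + 1)
  arch <- .weather_archetype(world, climate$tmax_c, climate$prec_mm)
  n_days <- nrow(climate)
  series <- list(); jumps <- list(); gaps <- list()
  for (tr in seq_len(world$n_trees)) {
    id <- paste0("T", tr)
    base <- 200 + 5 * tr
    vals <- numeric(n_days * 48)
    last <- base
    for (d in seq_len(n_days)) {
      cyc <- world$archetypes[arch[d] + 1, ] +
        stats::rnorm(48, sd = world$noise_sd)
      cyc[1] <- 0
      vals[((d - 1) * 48 + 1):(d * 48)] <- last + cyc
      last <- vals[d * 48]
    }
    ts <- seq(as.POSIXct(paste(climate$date[1], "00:00:00"), tz = "UTC"),
              by = 1800, length.out = n_days * 48)
    # jumps: +/- 5 mm level shifts at fixed interior fractions of the span
    # (kept clear of the injected gap windows so the artefacts stay separable)
    if (world$jumps_per_tree > 0) {
      jfrac <- seq(0.38, 0.72, length.out = world$jumps_per_tree)
      jpos <- round(n_days * 48 * jfrac) + tr * 13
      jmag <- sample(c(-5, 5), world$jumps_per_tree, replace = TRUE)
      for (q in seq_along(jpos))
        vals[jpos[q]:length(vals)] <- vals[jpos[q]:length(vals)] + jmag[q]
      jumps[[id]] <- data.frame(tree_id = id, timestamp = ts[jpos],
                                step_mm = jmag)
    } else jumps[[id]] <- NULL
    # gaps: short (6 h = 12 steps) and long (48 h = 96 steps), staggered by
    # tree so the other trees cover every long gap
    gap_rows <- list()
    ng_short <- world$gaps_per_tree[["short"]]
    ng_long <- world$gaps_per_tree[["long"]]
    span <- n_days * 48
    offs <- round(span * (0.2 + 0.5 * (tr - 1) / max(1, world$n_trees)))
    starts <- c(if (ng_short > 0)
                  round(seq(span * 0.15, span * 0.85,
                            length.out = ng_short)) + tr * 97,
                if (ng_long > 0) offs + seq_len(ng_long) * 531)
    lens <- c(rep(12, ng_short), rep(96, ng_long))
    for (g in seq_along(starts)) {
      gi <- starts[g]:(starts[g] + lens[g] - 1)
      gi <- gi[gi > 48 & gi < span - 48]
      vals_na <- gi
      vals[vals_na] <- NA
      gap_rows[[g]] <- data.frame(tree_id = id, start = ts[gi[1]],
                                  end = ts[gi[length(gi)]],
                                  steps = length(gi))
    }
    gaps[[id]] <- do.call(rbind, gap_rows)
    series[[id]] <- data.frame(timestamp = ts, tree_id = id,
                               circumference_mm = vals,
                               stringsAsFactors = FALSE)
  }
  labels <- do.call(rbind, lapply(names(series), function(id)
    data.frame(tree_id = id, date = climate$date, archetype = arch)))
  # construction truth: noise-free monthly growth vs true GC-day counts
  ym <- .year_month(climate$date)
  net <- world$nets[arch + 1]
  gc_day <- arch %in% c(1L, 3L)
  monthly <- data.frame(
    month = sort(unique(ym)),
    growth_mm = as.numeric(tapply(net, ym, sum)[sort(unique(ym))]),
    gc_days = as.numeric(tapply(gc_day, ym, sum)[sort(unique(ym))]) *
      world$n_trees)
  slope <- unname(stats::coef(stats::lm(growth_mm ~ gc_days,
                                        data = monthly))[2])
  list(series = series,
       truth = list(labels = labels, jumps = do.call(rbind, jumps),
                    gaps = do.call(rbind, gaps), monthly = monthly,
                    slope = slope))
}

# recycle the observed years' daily values onto future dates by month-day
# lookup (Feb 29 falls back to Feb 28 when the source year is not leap)
.recycle_climatology <- function(climate, dates) {
  yrs <- sort(unique(as.integer(format(climate$date, "%Y"))))
  key <- paste(format(climate$date, "%m-%d"),
               as.integer(format(climate$date, "%Y")))
  lut <- stats::setNames(seq_len(nrow(climate)), key)
  y_f <- as.integer(format(dates, "%Y"))
  src_year <- yrs[(y_f - yrs[1]) %% length(yrs) + 1]
  md <- format(dates, "%m-%d")
  idx <- lut[paste(md, src_year)]
  miss <- is.na(idx)
  idx[miss] <- lut[paste("02-28", src_year[miss])]
  unname(idx)
}

#' Generate synthetic climate-model output
#'
#' The historical simulation equals the station climate plus an additive
#' temperature bias with noise and a multiplicative precipitation bias with
#' wet-day thinning. Scenario series to 2100 recycle the observed
#' climatology with a linear warming trend and precipitation scaling per
#' scenario, then receive the same model bias. Monthly candidate tables (the
#' biased model and a no-skill shuffled reference) are emitted for model
#' ranking.
#'
#' @param world a [synthetic_world()].
#' @param climate a [gen_climate()] data.frame.
#' @param end_year last scenario year.
#' @return list: `monthly_candidates` (named list for [rank_gcms()]),
#'   `historical` (daily list per variable: data.frame `date`, `value`),
#'   `scenarios` (per SSP: daily simulated tmin/tmax/prec to `end_year`) and
#'   `scenario_truth` (same dates, the trend-shifted station series without
#'   model bias).
#' @export
gen_gcm <- function(world, climate, end_year = 2100) {
  set.seed(world$seed + 2)
  n <- nrow(climate)
  sim_tmax <- climate$tmax_c + world$temp_bias +
    stats::rnorm(n, sd = world$temp_noise_sd)
  sim_tmin <- climate$tmin_c + world$temp_bias +
    stats::rnorm(n, sd = world$temp_noise_sd)
  thin <- stats::runif(n) < world$prec_keep
  sim_prec <- ifelse(climate$prec_mm > 0 & thin,
                     climate$prec_mm * world$prec_bias, 0)
  false_wet <- climate$prec_mm == 0 & stats::runif(n) < world$prec_false_wet
  sim_prec[false_wet] <- stats::rgamma(sum(false_wet), 0.8, scale = 1.5)
  historical <- list(
    tmin = data.frame(date = climate$date, value = sim_tmin),
    tmax = data.frame(date = climate$date, value = sim_tmax),
    prec = data.frame(date = climate$date, value = sim_prec))
  # monthly candidates for KGE ranking
  sim_daily <- data.frame(date = climate$date, tmin_c = sim_tmin,
                          tmax_c = sim_tmax, prec_mm = sim_prec)
  good <- monthly_climate(sim_daily)
  shuffle <- sample.int(nrow(climate))
  noisy_daily <- data.frame(date = climate$date,
                            tmin_c = climate$tmin_c[shuffle],
                            tmax_c = climate$tmax_c[shuffle],
                            prec_mm = climate$prec_mm[shuffle])
  noise_cand <- monthly_climate(noisy_daily)
  to_cand <- function(m) data.frame(date = .month_date(m$month),
                                    tmin_c = m$tmin_c, tmax_c = m$tmax_c,
                                    prec_mm = m$prec_mm)
  # scenario series: recycled climatology + trend + model bias
  fdates <- seq(climate$date[1], as.Date(sprintf("%d-12-31", end_year)),
                by = "day")
  idx <- .recycle_climatology(climate, fdates)
  y_f <- as.integer(format(fdates, "%Y"))
  y0 <- world$start_year + world$years - 1
  frac <- pmax(0, (y_f - y0) / (end_year - y0))
  scenarios <- list(); scenario_truth <- list()
  for (ssp in names(world$ssp_warming)) {
    warm <- world$ssp_warming[[ssp]] * frac
    pfac <- 1 + (world$ssp_prec_factor[[ssp]] - 1) * frac
    t_tmin <- climate$tmin_c[idx] + warm
    t_tmax <- climate$tmax_c[idx] + warm
    t_prec <- climate$prec_mm[idx] * pfac
    m <- length(fdates)
    s_tmin <- t_tmin + world$temp_bias +
      stats::rnorm(m, sd = world$temp_noise_sd)
    s_tmax <- t_tmax + world$temp_bias +
      stats::rnorm(m, sd = world$temp_noise_sd)
    keep <- stats::runif(m) < world$prec_keep
    s_prec <- ifelse(t_prec > 0 & keep, t_prec * world$prec_bias, 0)
    scenario_truth[[ssp]] <- data.frame(date = fdates, tmin_c = t_tmin,
                                        tmax_c = t_tmax, prec_mm = t_prec)
    scenarios[[ssp]] <- list(
      tmin = data.frame(date = fdates, value = s_tmin),
      tmax = data.frame(date = fdates, value = s_tmax),
      prec = data.frame(date = fdates, value = s_prec))
  }
  list(monthly_candidates = list(biased_model = to_cand(good),
                                 shuffled_reference = to_cand(noise_cand)),
       historical = historical, scenarios = scenarios,
       scenario_truth = scenario_truth)
}
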