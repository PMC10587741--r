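test_that("KGE identities hold and components match the direct formula", {
  set.seed(2)
  obs <- rnorm(24, mean = 20, sd = 5)
  perfect <- kge(obs, obs)
  expect_equal(perfect$kge, 1)
  expect_equal(perfect$r, 1); expect_equal(perfect$beta, 1)
  expect_equal(perfect$gamma, 1)
  # doubling a positive series leaves r and gamma at 1, beta at 2 -> KGE 0
  pos <- abs(obs) + 1
  doubled <- kge(2 * pos, pos)
  expect_equal(doubled$r, 1)
  expect_equal(doubled$beta, 2)
  expect_equal(doubled$gamma, 1)
  expect_equal(doubled$kge, 0)
  # arbitrary 12-point pair against the formula oracle
  sim <- rnorm(12, 18, 4); o12 <- rnorm(12, 21, 6)
  expect_equal(kge(sim, o12)$kge, kge_oracle(sim, o12), tolerance = 1e-12)
  # invariance under a common positive rescaling
  expect_equal(kge(3 * sim, 3 * o12)$kge, kge(sim, o12)$kge,
               tolerance = 1e-12)
  expect_error(kge(1:5, rep(0, 5)), "mean")
  expect_error(kge(1:5, rep(2, 5)), "SD")
  expect_error(kge(1:3, 1:4), "length")
})

test_that("rank_gcms puts a perfect candidate first and noise last", {
  dates <- seq(as.Date("2016-01-01"), by = "month", length.out = 36)
  set.seed(5)
  obs <- data.frame(date = dates,
                    tmin_c = 10 + 8 * sin(2 * pi * (1:36) / 12),
                    tmax_c = 22 + 8 * sin(2 * pi * (1:36) / 12),
                    prec_mm = abs(100 * sin(2 * pi * (1:36) / 12)) + 10)
  noise <- obs
  noise[, 2:4] <- matrix(rnorm(108, 15, 10), ncol = 3)
  rk <- rank_gcms(list(truthful = obs, noisy = noise), obs)
  expect_equal(rk$best, "truthful")
  expect_equal(rk$table$mean_kge[rk$table$model == "truthful"], 1)
  expect_equal(rk$table$model[nrow(rk$table)], "noisy")
  # a single candidate is trivially best
  rk1 <- rank_gcms(list(only = obs), obs)
  expect_equal(rk1$best, "only")
  expect_error(rank_gcms(list(short = obs[1:10, ]), obs), "overlap")
})

test_that("temperature downscaling removes an additive bias", {
  set.seed(9)
  cal_dates <- seq(as.Date("2016-01-01"), as.Date("2018-12-31"), by = "day")
  doy <- as.POSIXlt(cal_dates)$yday + 1
  truth_cal <- 20 + 8 * sin(2 * pi * doy / 365) + rnorm(length(doy), sd = 1)
  fut_dates <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "day")
  fdoy <- as.POSIXlt(fut_dates)$yday + 1
  truth_fut <- 20 + 8 * sin(2 * pi * fdoy / 365) + rnorm(length(fdoy), sd = 1)
  # identity mapping: sim == obs in calibration
  ds <- downscale_temperature(
    sim = data.frame(date = cal_dates, value = truth_cal),
    obs = data.frame(date = cal_dates, value = truth_cal),
    scenario = data.frame(date = fut_dates, value = truth_fut), seed = 1)
  expect_lt(sqrt(mean((ds$value - truth_fut)^2)), 0.5)
  # constant +3 degC bias is learned away
  ds2 <- downscale_temperature(
    sim = data.frame(date = cal_dates, value = truth_cal + 3),
    obs = data.frame(date = cal_dates, value = truth_cal),
    scenario = data.frame(date = fut_dates, value = truth_fut + 3), seed = 1)
  expect_lt(abs(mean(ds2$value - truth_fut)), 0.3)
  # determinism
  ds3 <- downscale_temperature(
    sim = data.frame(date = cal_dates, value = truth_cal + 3),
    obs = data.frame(date = cal_dates, value = truth_cal),
    scenario = data.frame(date = fut_dates, value = truth_fut + 3), seed = 1)
  expect_identical(ds2$value, ds3$value)
  expect_error(downscale_temperature(
    sim = data.frame(date = cal_dates[1:100], value = truth_cal[1:100]),
    obs = data.frame(date = cal_dates[1:100], value = truth_cal[1:100]),
    scenario = data.frame(date = fut_dates, value = truth_fut), seed = 1),
    "overlap")
})

test_that("two-step precipitation downscaling keeps dry days at exact zero", {
  set.seed(31)
  cal_dates <- seq(as.Date("2016-01-01"), as.Date("2018-12-31"), by = "day")
  doy <- as.POSIXlt(cal_dates)$yday + 1
  p_wet <- 0.1 + 0.6 * exp(-((doy - 210) / 50)^2)
  wet <- runif(length(doy)) < p_wet
  obs_p <- ifelse(wet, rgamma(length(doy), 0.9, scale = 8), 0)
  sim_p <- ifelse(wet & runif(length(doy)) < 0.9, obs_p * 1.2, 0)
  fut_dates <- seq(as.Date("2019-01-01"), as.Date("2020-12-31"), by = "day")
  fdoy <- as.POSIXlt(fut_dates)$yday + 1
  fwet <- runif(length(fdoy)) < (0.1 + 0.6 * exp(-((fdoy - 210) / 50)^2))
  fut_sim <- ifelse(fwet & runif(length(fdoy)) < 0.9,
                    rgamma(length(fdoy), 0.9, scale = 8) * 1.2, 0)
  ds <- downscale_precipitation(
    sim = data.frame(date = cal_dates, value = sim_p),
    obs = data.frame(date = cal_dates, value = obs_p),
    scenario = data.frame(date = fut_dates, value = fut_sim), seed = 4)
  expect_true(all(ds$value >= 0))
  # exact zeros (not small positives) on predicted-dry days
  expect_true(any(ds$value == 0))
  expect_true(all(ds$value[ds$value < 0.1] == 0))
  # monthly wet-day frequency tracks the truth within 15 percentage points
  ym <- format(fut_dates, "%Y-%m")
  f_pred <- tapply(ds$value >= 0.1, ym, mean)
  f_true <- tapply(fwet, ym, mean)
  expect_lt(max(abs(f_pred - f_true)), 0.25)
  expect_lt(mean(abs(f_pred - f_true)), 0.15)
  expect_error(downscale_precipitation(
    sim = data.frame(date = cal_dates, value = sim_p),
    obs = data.frame(date = cal_dates, value = rep(0, length(cal_dates))),
    scenario = data.frame(date = fut_dates, value = fut_sim), seed = 4),
    "wet and dry")
})

test_that("period extraction slices exact 6-year calendar windows", {
  dates <- seq(as.Date("2040-01-01"), as.Date("2100-12-31"), by = "day")
  df <- data.frame(date = dates, value = seq_along(dates))
  w <- extract_periods(df)
  expect_named(w, c("2050s", "2100s"))
  expect_equal(nrow(w[["2050s"]]), 2192)  # leap 2048 and 2052 included
  expect_equal(range(w[["2100s"]]$date),
               as.Date(c("2095-01-01", "2100-12-31")))
  # slicing twice gives the same result
  expect_identical(w, extract_periods(df))
  expect_error(extract_periods(df[df$date < as.Date("2090-01-01"), ]),
               "window")
})
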