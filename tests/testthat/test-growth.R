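test_that("monthly growth sums DCC per tree and averages across trees", {
  dates <- seq(as.Date("2020-04-01"), as.Date("2020-04-30"), by = "day")
  d1 <- data.frame(tree_id = "T1", date = dates, morning_max_mm = NA,
                   dcc_mm = rep(0.1, 30))
  expect_equal(monthly_growth(list(d1))$gro_mm, 3.0)
  d2 <- data.frame(tree_id = "T2", date = dates, morning_max_mm = NA,
                   dcc_mm = rep(0.2, 30))  # 6.0 mm month
  m <- monthly_growth(list(half = within(d1, dcc_mm <- dcc_mm * 2 / 3),
                           d2 = d2))
  expect_equal(m$gro_mm, mean(c(2.0, 6.0)))
  expect_equal(m$n_trees, 2L)
  # a tree absent in a month leaves the mean over the remaining trees
  d3 <- data.frame(tree_id = "T3",
                   date = seq(as.Date("2020-05-01"), by = "day",
                              length.out = 31),
                   morning_max_mm = NA, dcc_mm = 0.1)
  m2 <- monthly_growth(list(d1, d3))
  expect_equal(m2$n_trees, c(1L, 1L))
  expect_error(monthly_growth(list()), "empty")
})

test_that("count-growth correlations hit the exact limits", {
  months <- format(seq(as.Date("2016-01-01"), by = "month",
                       length.out = 24), "%Y-%m")
  counts <- data.frame(month = months, gc = 1:24, ngc = 24:1)
  gro <- data.frame(month = months, gro_mm = 2 * (1:24) + 5)
  cc <- correlate_counts_growth(counts, gro)
  expect_equal(cc$r[cc$term == "gc"], 1)
  expect_equal(cc$r[cc$term == "ngc"], -1)
  expect_error(correlate_counts_growth(counts[1:5, ], gro), "12")
})

test_that("the growth model recovers a planted slope", {
  months <- format(seq(as.Date("2016-01-01"), by = "month",
                       length.out = 60), "%Y-%m")
  set.seed(4)
  counts <- data.frame(month = months,
                       count = round(runif(60, 0, 60)))
  # zero noise: exact recovery
  gro0 <- data.frame(month = months, gro_mm = 0.2 + 0.05 * counts$count)
  fit0 <- fit_growth_model(gro0, counts)
  expect_equal(fit0$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0.2, tolerance = 1e-12)
  # noise sigma = 0.01: slope within +/- 0.005
  gro1 <- data.frame(month = months,
                     gro_mm = 0.2 + 0.05 * counts$count + rnorm(60, sd = 0.01))
  fit1 <- fit_growth_model(gro1, counts)
  expect_lt(abs(fit1$slope - 0.05), 0.005)
  expect_error(fit_growth_model(gro0, transform(counts, count = 5)),
               "rank deficient")
  expect_error(fit_growth_model(gro0[1:6, ], counts[1:6, ]), "12")
})

test_that("slope recovery holds across repeated seeded simulations", {
  months <- format(seq(as.Date("2016-01-01"), by = "month",
                       length.out = 60), "%Y-%m")
  set.seed(123)
  slopes <- r2s <- numeric(100)
  for (i in 1:100) {
    counts <- data.frame(month = months, count = round(runif(60, 0, 60)))
    gro <- data.frame(month = months,
                      gro_mm = 0.1 + 0.05 * counts$count +
                        rnorm(60, sd = 0.02))
    fit <- fit_growth_model(gro, counts)
    slopes[i] <- fit$slope
    r2s[i] <- blocked_cv(gro, counts)$summary$mean[1]
  }
  expect_lt(abs(mean(slopes) / 0.05 - 1), 0.05)  # bias < 5%
  expect_gte(mean(r2s), 0.5)
  expect_lte(mean(r2s), 1)
})

test_that("blocked CV partitions months contiguously and exactly", {
  months <- format(seq(as.Date("2016-01-01"), by = "month",
                       length.out = 23), "%Y-%m")
  counts <- data.frame(month = months, count = seq_along(months))
  gro <- data.frame(month = months, gro_mm = 1 + 0.3 * seq_along(months))
  cv <- blocked_cv(gro, counts, folds = 10)
  expect_equal(nrow(cv$per_fold), 10)
  expect_equal(sum(cv$per_fold$n), 23)
  # remainder months go one per block from the first: sizes 3,3,3,2,...
  expect_equal(cv$per_fold$n, c(3, 3, 3, rep(2, 7)))
  # noiseless linear relation: every fold perfect
  expect_true(all(abs(cv$per_fold$r2 - 1) < 1e-9))
  expect_true(all(abs(cv$per_fold$ve - 1) < 1e-9))
  expect_true(all(cv$per_fold$rmse < 1e-9))
  expect_error(blocked_cv(gro[1:15, ], counts[1:15, ]), "20")
})

test_that("CV error matches the planted noise level", {
  months <- format(seq(as.Date("2016-01-01"), by = "month",
                       length.out = 60), "%Y-%m")
  set.seed(8)
  counts <- data.frame(month = months, count = round(runif(60, 0, 60)))
  sigma <- 0.05
  gro <- data.frame(month = months,
                    gro_mm = 0.1 + 0.04 * counts$count +
                      rnorm(60, sd = sigma))
  cv <- blocked_cv(gro, counts)
  expect_lt(cv$summary$mean[cv$summary$metric == "rmse"], 2 * sigma)
})

test_that("growth projection reproduces closed-form scenario changes", {
  months <- format(seq(as.Date("2016-01-01"), by = "month",
                       length.out = 24), "%Y-%m")
  set.seed(10)
  counts <- data.frame(month = months, count = round(runif(24, 10, 50)))
  gro <- data.frame(month = months, gro_mm = 0.05 * counts$count)
  model <- fit_growth_model(gro, counts)  # zero intercept, slope 0.05
  fut <- data.frame(month = sub("2016|2017", "2050", months),
                    count = counts$count)
  pr_same <- project_growth(model, fut, gro)
  expect_true(all(abs(pr_same$pct_change) < 1e-9))
  expect_equal(attr(pr_same, "total_pct_change"), 0, tolerance = 1e-9)
  # doubled counts under a zero intercept: +100% every month
  fut2 <- transform(fut, count = count * 2)
  pr_double <- project_growth(model, fut2, gro)
  expect_true(all(abs(pr_double$pct_change - 100) < 1e-6))
  expect_equal(attr(pr_double, "total_pct_change"), 100, tolerance = 1e-6)
})

test_that("delta-day statistics use the population SD convention", {
  expect_equal(delta_day_stats(c(5, 5, 5)), c(mean = 5, sd = 0))
  expect_equal(delta_day_stats(c(-2, 2)), c(mean = 0, sd = 2))
  expect_error(delta_day_stats(7), "2 scenarios")
})
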