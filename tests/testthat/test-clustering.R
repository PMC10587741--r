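test_that("day matrix rows are zero-anchored complete tree-days", {
  s <- make_series(rep(7.5, 48))
  dm <- build_day_matrix(list(s))
  expect_equal(dim(dm$values), c(1, 48))
  expect_equal(dm$values[1, ], rep(0, 48))
  # same shape at different absolute levels -> identical rows
  shape <- sin(seq(0, 2 * pi, length.out = 48))
  dm2 <- build_day_matrix(list(make_series(100 + shape),
                               make_series(250 + shape, tree_id = "T2")))
  expect_equal(dm2$values[1, ], dm2$values[2, ])
  # a 47-reading day is dropped and counted
  s3 <- make_series(rep(1, 95))  # one complete day + one 47-reading day
  dm3 <- build_day_matrix(list(s3))
  expect_equal(nrow(dm3$values), 1)
  expect_equal(dm3$dropped, 1L)
  expect_error(build_day_matrix(list()), "empty")
})

test_that("dtw_distance matches the brute-force DP oracle", {
  expect_equal(dtw_distance(1:5, 1:5), 0)
  a <- c(0, 0, 1); b <- c(0, 1, 1)
  expect_equal(dtw_distance(a, b), dtw_oracle(a, b))
  set.seed(42)
  for (i in 1:40) {
    n <- sample(2:10, 1); m <- sample(2:10, 1)
    a <- rnorm(n); b <- rnorm(m)
    expect_equal(dtw_distance(a, b), dtw_oracle(a, b), tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_gte(dtw_distance(a, b), 0)
  }
  expect_error(dtw_distance(c(1, NA), c(1, 2)), "finite")
})

test_that("a constant offset over 48 points costs delta * sqrt(48)", {
  set.seed(1)
  a <- cumsum(rnorm(48, sd = 0.05))
  delta <- 3  # large offset: the optimal path is the diagonal
  b <- a + delta
  expect_equal(dtw_distance(a, b), dtw_oracle(a, b))
  expect_equal(dtw_distance(a, b), delta * sqrt(48), tolerance = 1e-6)
})

test_that("two exact archetypes split perfectly at k = 2 with zero inertia", {
  r1 <- sin(seq(0, pi, length.out = 48)); r1 <- r1 - r1[1]
  r2 <- seq(0, 1, length.out = 48)
  X <- rbind(r1, r1, r1, r2, r2, r2)
  dm <- structure(list(values = X,
                       keys = data.frame(tree_id = "T1",
                                         date = as.Date("2020-01-01") + 0:5),
                       dropped = 0L), class = "day_matrix")
  m <- cluster_days(dm, k = 2, seed = 1, n_init = 2, max_iter = 20)
  expect_equal(m$inertia, 0, tolerance = 1e-10)
  expect_equal(length(unique(m$labels[1:3])), 1)
  expect_equal(length(unique(m$labels[4:6])), 1)
  expect_false(m$labels[1] == m$labels[4])
  # determinism: same seed reproduces labels exactly
  m2 <- cluster_days(dm, k = 2, seed = 1, n_init = 2, max_iter = 20)
  expect_identical(m$labels, m2$labels)
  expect_error(cluster_days(dm, k = 1, seed = 1), "k must be")
  expect_error(cluster_days(dm, k = 10, seed = 1), "k must be")
})

test_that("planted archetypes are recovered on the synthetic world", {
  fit <- small_world_fit()
  ari <- adjusted_rand(fit$model$labels, fit$truth_rows)
  expect_gte(ari, 0.9)
  # best-of-restarts inertia is no worse than a single-restart fit
  m1 <- cluster_days(fit$dm, k = 4, seed = 3, n_init = 1, max_iter = 30)
  expect_lte(fit$model$inertia, m1$inertia + 1e-9)
})

test_that("the elbow rule picks the planted k and handles degenerate curves", {
  fit <- small_world_fit()
  k <- elbow_select_k(fit$dm, k_range = 2:8, seed = 5, n_init = 2,
                      max_iter = 30)
  expect_equal(as.integer(k), 4L)
  # inertia is recorded for every candidate
  expect_equal(length(attr(k, "inertia")), 7)
  # linear decay -> smallest k with a warning
  expect_warning(k_lin <- intragro:::.elbow_pick(2:8, seq(70, 10, by = -10)),
                 "elbow")
  expect_equal(k_lin, 2L)
  # flat curve -> smallest k with a warning
  expect_warning(k_flat <- intragro:::.elbow_pick(2:8, rep(5, 7)), "elbow")
  expect_equal(k_flat, 2L)
  expect_error(elbow_select_k(fit$dm, k_range = 2:3, seed = 1), "at least 3")
})

test_that("a two-archetype world yields no deeper elbow than k = 2", {
  world <- synthetic_world(seed = 21, years = 1, n_trees = 1,
                           jumps_per_tree = 0,
                           gaps_per_tree = c(short = 0, long = 0))
  climate <- gen_climate(world)
  dendro <- gen_dendrometer(world, climate)
  s <- dendro$series[[1]]
  keep <- dendro$truth$labels$archetype %in% c(0L, 1L)
  days_keep <- dendro$truth$labels$date[keep]
  s <- s[as.Date(s$timestamp, tz = "UTC") %in% days_keep, ]
  dm <- build_day_matrix(list(s))
  expect_warning(k <- elbow_select_k(dm, 2:6, seed = 2, n_init = 2,
                                     max_iter = 20), "elbow")
  expect_equal(as.integer(k), 2L)
})

test_that("groups cover all clusters disjointly and follow the mean sign", {
  fit <- small_world_fit()
  g <- assign_groups(fit$model, fit$dm)
  expect_setequal(g$cluster, 0:3)
  expect_true(all(g$group %in% c("GC", "NGC")))
  # direct-averaging oracle for the net change
  net <- fit$dm$values[, 48]
  for (i in seq_len(nrow(g))) {
    expect_equal(g$net_change_mm[i], mean(net[fit$model$labels == g$cluster[i]]))
  }
  expect_identical(g$group, ifelse(g$net_change_mm > 5e-3, "GC", "NGC"))
  # rows ending exactly at zero tie to non-growing
  X <- rbind(matrix(0, 3, 48), matrix(rep(seq(0, 1, length.out = 48), 3),
                                      3, byrow = TRUE))
  dm0 <- structure(list(values = X,
                        keys = data.frame(tree_id = "T1",
                                          date = as.Date("2020-01-01") + 0:5),
                        dropped = 0L), class = "day_matrix")
  m0 <- cluster_days(dm0, 2, seed = 1, n_init = 2)
  g0 <- assign_groups(m0, dm0)
  flat_cluster <- m0$labels[1]
  expect_equal(g0$group[g0$cluster == flat_cluster], "NGC")
})

test_that("cluster-climate tests: counts, letters and a calibrated null", {
  # k = 4 -> 6 pairwise comparisons; disjoint ranges -> distinct letters
  labels <- rep(0:3, each = 30)
  clim <- data.frame(tmin_c = rnorm(120),
                     tmax_c = rep(c(0, 10, 20, 30), each = 30) +
                       runif(120, 0, 1),
                     prec_mm = abs(rnorm(120)))
  ct <- cluster_climate_tests(labels, clim)
  expect_equal(nrow(ct$tmax_c$dunn), 6)
  expect_true(all(ct$tmax_c$dunn$p_adj < 0.05))
  expect_equal(length(unique(ct$tmax_c$letters)), 4)
  expect_true(all(ct$tmax_c$dunn$p_adj >= ct$tmax_c$dunn$p))
  # two clusters from the same distribution: rejection rate near alpha
  set.seed(404)
  rej <- mean(replicate(200, {
    x <- rnorm(40)
    kruskal.test(x, factor(rep(1:2, each = 20)))$p.value < 0.05
  }))
  expect_gte(rej, 0.005)
  expect_lte(rej, 0.11)
  expect_error(cluster_climate_tests(rep(0, 10), clim[1:10, ]), ">= 2")
})
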