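#' Run the full growth-projection pipeline
#'
#' Orchestrates every stage on synthetic inputs: generate climate, dendrometer
#' series and climate-model output; preprocess (gap filling, jump removal,
#' DCC); build the day matrix; select k by the elbow method (or use a fixed
#' k); cluster with DTW k-means; assign growing / non-growing groups; train
#' the climate-to-cluster classifier; evaluate and downscale the climate
#' model; predict future daily clusters; fit, cross-validate and project the
#' linear growth model; and derive growing-season dates for the observed and
#' scenario windows. Randomness at every stage is derived from `seed`, so a
#' rerun with the same configuration is identical.
#'
#' @param seed integer master seed.
#' @param years,n_trees synthetic world size.
#' @param k number of clusters, or `"auto"` for elbow selection.
#' @param k_range candidate k values when `k = "auto"`.
#' @param n_init,max_iter k-means restarts/iterations.
#' @param ssps scenario names to project.
#' @param out_dir optional directory; when given, stage outputs are written
#'   as CSV/JSON with a manifest.
#' @param latitude site latitude (for PET / moisture index enrichment).
#' @param verbose print per-stage progress.
#' @return (invisibly) a list with every intermediate and final artifact;
#'   see the stage functions for the individual structures.
#' @export
run_pipeline <- function(seed = 42, years = 5, n_trees = 4,
                         k = "auto", k_range = 2:8, n_init = 5,
                         max_iter = 50,
                         ssps = c("ssp126", "ssp245", "ssp370", "ssp585"),
                         out_dir = NULL, latitude = 27.68, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  say("[simulate] %d years, %d trees (seed %d)", years, n_trees, seed)
  world <- synthetic_world(seed = seed, years = years, n_trees = n_trees)
  climate <- gen_climate(world)
  climate$pet_mm <- hargreaves_pet(climate$date, latitude,
                                   climate$tmin_c, climate$tmax_c)
  climate$mi_mm <- moisture_index(climate$prec_mm, climate$pet_mm)
  dendro <- gen_dendrometer(world, climate)
  gcm <- gen_gcm(world, climate)

  say("[preprocess] gap filling, jump removal, DCC")
  clean <- lapply(names(dendro$series), function(id) {
    peers <- dendro$series[setdiff(names(dendro$series), id)]
    s <- fill_gaps(dendro$series[[id]], peers = peers)
    remove_jumps(s, jump_threshold = 1.0)
  })
  names(clean) <- names(dendro$series)
  dcc <- lapply(clean, daily_circumference_change)

  say("[cluster] day matrix + DTW k-means")
  dm <- build_day_matrix(clean)
  if (identical(k, "auto")) {
    k_sel <- elbow_select_k(dm, k_range = k_range, seed = seed + 10,
                            max_iter = max_iter)
  } else {
    k_sel <- as.integer(k)
  }
  model <- cluster_days(dm, k = as.integer(k_sel), seed = seed + 10,
                        n_init = n_init, max_iter = max_iter)
  groups <- assign_groups(model, dm)
  key_climate <- climate[match(dm$keys$date, climate$date), ]
  ctests <- cluster_climate_tests(model$labels, key_climate)

  say("[classify] random-forest climate -> cluster")
  features <- data.frame(tmin_c = key_climate$tmin_c,
                         tmax_c = key_climate$tmax_c,
                         prec_mm = key_climate$prec_mm,
                         month = as.integer(format(dm$keys$date, "%m")))
  clf <- train_classifier(features, model$labels, seed = seed + 20)

  say("[evaluate-gcm] KGE ranking + downscaling")
  obs_monthly <- monthly_climate(climate)
  obs_cand <- data.frame(date = .month_date(obs_monthly$month),
                         tmin_c = obs_monthly$tmin_c,
                         tmax_c = obs_monthly$tmax_c,
                         prec_mm = obs_monthly$prec_mm)
  ranking <- rank_gcms(gcm$monthly_candidates, obs_cand)
  obs_v <- list(tmin = data.frame(date = climate$date, value = climate$tmin_c),
                tmax = data.frame(date = climate$date, value = climate$tmax_c),
                prec = data.frame(date = climate$date, value = climate$prec_mm))
  downscaled <- list()
  for (ssp in ssps) {
    sc <- gcm$scenarios[[ssp]]
    dtmin <- downscale_temperature(gcm$historical$tmin, obs_v$tmin,
                                   sc$tmin, seed = seed + 30)
    dtmax <- downscale_temperature(gcm$historical$tmax, obs_v$tmax,
                                   sc$tmax, seed = seed + 31)
    dprec <- downscale_precipitation(gcm$historical$prec, obs_v$prec,
                                     sc$prec, seed = seed + 32)
    downscaled[[ssp]] <- data.frame(
      date = sc$tmin$date,
      tmin_c = pmin(dtmin$value, dtmax$value),
      tmax_c = pmax(dtmin$value, dtmax$value),
      prec_mm = dprec$value)
  }

  say("[predict] future daily clusters per scenario window")
  future <- list()
  for (ssp in ssps) {
    wins <- extract_periods(downscaled[[ssp]])
    future[[ssp]] <- lapply(wins, function(w) predict_clusters(clf, w))
  }

  say("[project] growth model + cross-validation + scenarios")
  gro <- monthly_growth(dcc)
  lab_month <- .year_month(dm$keys$date)
  gc_clusters <- groups$cluster[groups$group == "GC"]
  is_gc <- model$labels %in% gc_clusters
  gc_counts <- data.frame(
    month = sort(unique(lab_month)),
    count = as.numeric(tapply(is_gc, lab_month, sum)[sort(unique(lab_month))]))
  gmodel <- fit_growth_model(gro, gc_counts)
  cv <- blocked_cv(gro, gc_counts)
  n_model_trees <- length(clean)
  projections <- list()
  for (ssp in ssps) {
    projections[[ssp]] <- lapply(future[[ssp]], function(fc) {
      mc <- fc$monthly_counts
      gc_cols <- as.character(gc_clusters)
      gc_cols <- gc_cols[gc_cols %in% names(mc)]
      # classifier sees one day per date; scale to the stacked per-tree count
      # convention of the calibration period
      cnt <- data.frame(month = mc$month,
                        count = rowSums(mc[, gc_cols, drop = FALSE]) *
                          n_model_trees)
      project_growth(gmodel, cnt, gro)
    })
  }

  say("[phenology] cumulative curves + season dates")
  obs_pts <- observed_cumulative_points(dcc)
  obs_curve <- fit_cumulative_curve(obs_pts$doy, obs_pts$cumulative_mm)
  obs_season <- season_dates(obs_curve)
  phen <- list(); deltas <- list()
  for (ssp in ssps) {
    phen[[ssp]] <- lapply(names(projections[[ssp]]), function(win) {
      pr <- projections[[ssp]][[win]]
      pts <- future_cumulative_points(pr$pred_gro_mm)
      curve <- fit_cumulative_curve(pts$doy, pts$cumulative_mm)
      sd <- season_dates(curve)
      list(curve = curve, season = sd,
           delta = compare_seasons(obs_season, sd))
    })
    names(phen[[ssp]]) <- names(projections[[ssp]])
  }
  delta_tab <- do.call(rbind, lapply(names(phen), function(ssp) {
    do.call(rbind, lapply(names(phen[[ssp]]), function(win) {
      d <- phen[[ssp]][[win]]$delta
      data.frame(scenario = ssp, period = win,
                 dsos = d[["dsos"]], deos = d[["deos"]], dgs = d[["dgs"]])
    }))
  }))
  delta_stats <- if (length(ssps) >= 2) {
    lapply(split(delta_tab, delta_tab$period), function(dd)
      list(sos = delta_day_stats(dd$dsos), eos = delta_day_stats(dd$deos)))
  } else NULL

  res <- list(seed = seed, world = world, climate = climate,
              dendro = dendro, gcm = gcm, clean = clean, dcc = dcc,
              day_matrix = dm, elbow_k = k_sel, cluster_model = model,
              groups = groups, climate_tests = ctests, classifier = clf,
              gcm_ranking = ranking, downscaled = downscaled,
              future_clusters = future, gro = gro, gc_counts = gc_counts,
              growth_model = gmodel, cv = cv, projections = projections,
              obs_season = obs_season, phenology = phen,
              season_deltas = delta_tab, delta_stats = delta_stats,
              elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                              units = "secs")))
  if (!is.null(out_dir)) .write_pipeline_artifacts(res, out_dir)
  say("[done] %.1f s", res$elapsed_s)
  invisible(res)
}

# write the stage outputs a downstream user would consume
.write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(res$climate, "climate_enriched.csv")
  cleaned <- do.call(rbind, res$clean)
  w(cleaned, "dendro_cleaned.csv")
  w(do.call(rbind, res$dcc), "dcc.csv")
  w(cbind(res$day_matrix$keys, cluster = res$cluster_model$labels,
          group = res$groups$group[match(res$cluster_model$labels,
                                         res$groups$cluster)]),
    "clusters.csv")
  w(as.data.frame(res$cluster_model$centroids), "centroids.csv")
  w(res$gcm_ranking$table, "gcm_ranking.csv")
  w(res$gro, "monthly_growth.csv")
  w(res$gc_counts, "monthly_gc_counts.csv")
  w(res$season_deltas, "season_deltas.csv")
  for (ssp in names(res$downscaled))
    w(res$downscaled[[ssp]], sprintf("downscaled_%s.csv", ssp))
  rep <- res$classifier$report_test
  jsonlite::write_json(
    list(per_class = rep$per_class, accuracy = rep$accuracy,
         macro = as.list(rep$macro), weighted = as.list(rep$weighted)),
    file.path(out_dir, "report_test.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(intercept = res$growth_model$intercept,
         slope = res$growth_model$slope,
         cv = res$cv$summary),
    file.path(out_dir, "growth_model.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = res$seed, years = res$world$years, n_trees = res$world$n_trees,
    k = res$cluster_model$k,
    package_version = as.character(utils::packageVersion("intragro")),
    elapsed_s = res$elapsed_s,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
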