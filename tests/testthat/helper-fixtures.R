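# Shared fixtures, built once per session and cached: a small synthetic
# world (one year, two trees) taken through preprocessing and clustering.

.fixture_env <- new.env(parent = emptyenv())

small_world_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  world <- synthetic_world(seed = 11, years = 1, n_trees = 2)
  climate <- gen_climate(world)
  dendro <- gen_dendrometer(world, climate)
  clean <- lapply(names(dendro$series), function(id) {
    peers <- dendro$series[setdiff(names(dendro$series), id)]
    remove_jumps(fill_gaps(dendro$series[[id]], peers = peers))
  })
  names(clean) <- names(dendro$series)
  dm <- build_day_matrix(clean)
  model <- cluster_days(dm, k = 4, seed = 3, n_init = 3, max_iter = 30)
  truth <- dendro$truth$labels
  truth_rows <- truth$archetype[match(
    paste(dm$keys$tree_id, dm$keys$date),
    paste(truth$tree_id, truth$date))]
  .fixture_env$fit <- list(world = world, climate = climate,
                           dendro = dendro, clean = clean, dm = dm,
                           model = model, truth_rows = truth_rows)
  .fixture_env$fit
}
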