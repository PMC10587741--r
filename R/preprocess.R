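#' Read a raw dendrometer CSV
#'
#' Expects columns `timestamp` (ISO 8601, local time), `tree_id` and
#' `circumference_mm`. Timestamps are parsed timezone-naive (stored as UTC).
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `timestamp` (POSIXct), `tree_id`
#'   (character) and `circumference_mm` (numeric).
#' @export
read_dendro_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "tree_id", "circumference_mm")
  if (!all(need %in% names(df)))
    stop("dendrometer CSV must have columns: ", paste(need, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                            "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                            "%Y-%m-%d"))  # midnight readings
  if (anyNA(df$timestamp)) stop("unparseable timestamps in ", path)
  df$tree_id <- as.character(df$tree_id)
  df[order(df$tree_id, df$timestamp), c("timestamp", "tree_id", "circumference_mm")]
}

#' Split a multi-tree dendrometer table into per-tree series
#'
#' @param df data.frame as returned by [read_dendro_csv()].
#' @return named list of single-tree data.frames.
#' @export
split_trees <- function(df) {
  split(df, df$tree_id)
}

# Snap a single-tree series onto the regular 30-min grid spanning its record.
# Readings are matched to the nearest grid node; unmatched nodes are NA.
.regularize_30min <- function(series) {
  ts <- series$timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("timestamps must be strictly increasing for tree ",
         series$tree_id[1])
  step <- 1800
  t0 <- round(as.numeric(ts[1]) / step) * step
  t1 <- round(as.numeric(ts[length(ts)]) / step) * step
  grid <- seq(t0, t1, by = step)
  idx <- round((as.numeric(ts) - t0) / step) + 1
  ok <- idx >= 1 & idx <= length(grid)
  vals <- rep(NA_real_, length(grid))
  vals[idx[ok]] <- series$circumference_mm[ok]
  data.frame(timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
             tree_id = series$tree_id[1],
             circumference_mm = vals,
             stringsAsFactors = FALSE)
}

# NA runs as (start index, end index) pairs
.na_runs <- function(x) {
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Fill gaps in a dendrometer series
#'
#' The series is snapped onto a regular 30-min grid. Gaps up to
#' `max_spline_hours` are filled by a cubic spline through the flanking
#' readings; longer gaps are reconstructed from the mean standardized course
#' of peer trees over the gap, rescaled to the target tree's level and spread
#' in a +/- 3-day window around the gap.
#'
#' @param series single-tree data.frame (`timestamp`, `tree_id`,
#'   `circumference_mm`), possibly with missing readings.
#' @param peers list of other trees' series used for long gaps.
#' @param max_spline_hours longest gap (hours) filled by spline.
#' @return gap-free data.frame on the 30-min grid, with a `fill_log`
#'   attribute describing each filled gap.
#' @export
fill_gaps <- function(series, peers = list(), max_spline_hours = 24) {
  reg <- .regularize_30min(series)
  x <- reg$circumference_mm
  n <- length(x)
  if (is.na(x[1]) || is.na(x[n]))
    stop("gaps must not cover the ends of the series")
  runs <- .na_runs(x)
  if (nrow(runs) == 0) {
    attr(reg, "fill_log") <- data.frame()
    return(reg)
  }
  max_steps <- max_spline_hours * 2
  peers_reg <- lapply(peers, .regularize_30min)
  log <- list()
  tnum <- as.numeric(reg$timestamp)
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, "start"]; b <- runs[r, "end"]
    len <- b - a + 1
    gap_idx <- a:b
    if (len <= max_steps) {
      # spline through up to 24 h of flanking readings on each side
      side <- 48
      lo <- max(1, a - side); hi <- min(n, b + side)
      known <- setdiff(lo:hi, which(is.na(x)))
      known <- known[known >= lo & known <= hi]
      fit <- stats::spline(tnum[known], x[known], xout = tnum[gap_idx],
                           method = "fmm")
      x[gap_idx] <- fit$y
      method <- "spline"
    } else {
      x[gap_idx] <- .network_fill(reg, x, gap_idx, peers_reg)
      method <- "network"
    }
    log[[r]] <- data.frame(start = reg$timestamp[a], end = reg$timestamp[b],
                           steps = len, method = method)
  }
  reg$circumference_mm <- x
  attr(reg, "fill_log") <- do.call(rbind, log)
  reg
}

# Long-gap reconstruction from peers: each peer covering the whole gap is
# z-standardized over the +/- 3-day window of target readings around the gap,
# the standardized courses are averaged, and the mean course is mapped back
# to the target's mean/sd over that window.
.network_fill <- function(reg, x, gap_idx, peers_reg) {
  tnum <- as.numeric(reg$timestamp)
  gap_t <- tnum[gap_idx]
  win <- 3 * 86400
  w_idx <- which(tnum >= min(gap_t) - win & tnum <= max(gap_t) + win)
  w_idx <- setdiff(w_idx, gap_idx)
  w_idx <- w_idx[!is.na(x[w_idx])]
  if (length(w_idx) < 4)
    stop("too few target readings around the long gap at ",
         format(reg$timestamp[gap_idx[1]]))
  m_t <- mean(x[w_idx]); s_t <- stats::sd(x[w_idx])
  zs <- list()
  for (p in peers_reg) {
    pt <- as.numeric(p$timestamp)
    gi <- match(gap_t, pt)
    wi <- match(tnum[w_idx], pt)
    if (anyNA(gi) || any(is.na(p$circumference_mm[gi]))) next
    wv <- p$circumference_mm[wi[!is.na(wi)]]
    wv <- wv[!is.na(wv)]
    if (length(wv) < 4) next
    m_p <- mean(wv); s_p <- stats::sd(wv)
    if (s_p == 0) next
    zs[[length(zs) + 1]] <- (p$circumference_mm[gi] - m_p) / s_p
  }
  if (length(zs) == 0)
    stop("no peer series overlaps the long gap starting at ",
         format(reg$timestamp[gap_idx[1]]),
         "; cannot network-interpolate")
  zbar <- Reduce(`+`, zs) / length(zs)
  if (s_t == 0) rep(m_t, length(gap_idx)) else zbar * s_t + m_t
}

#' Remove artificial jumps from a cleaned series
#'
#' Consecutive-reading differences larger in magnitude than `jump_threshold`
#' (band re-adjustments, battery swaps) are treated as artefacts: each step is
#' subtracted from all subsequent readings, so real variation within a step is
#' preserved while the level discontinuity is removed.
#'
#' @param series gap-free single-tree data.frame.
#' @param jump_threshold largest plausible true 30-min change (mm), > 0.
#' @return corrected data.frame with a `jump_log` attribute
#'   (`timestamp`, `step_mm` per removed jump).
#' @export
remove_jumps <- function(series, jump_threshold = 1.0) {
  if (!is.numeric(jump_threshold) || length(jump_threshold) != 1 ||
      jump_threshold <= 0)
    stop("jump_threshold must be a single positive number")
  x <- series$circumference_mm
  if (anyNA(x)) stop("remove_jumps expects a gap-free series")
  d <- diff(x)
  is_jump <- abs(d) > jump_threshold
  adj <- c(0, cumsum(ifelse(is_jump, d, 0)))
  out <- series
  out$circumference_mm <- x - adj
  attr(out, "jump_log") <-
    data.frame(timestamp = series$timestamp[which(is_jump) + 1],
               step_mm = d[is_jump])
  out
}

#' Daily morning maxima and daily circumference change (DCC)
#'
#' The morning maximum of a day is the largest reading between midnight and
#' `morning_end`. DCC is the difference between consecutive days' morning
#' maxima, attributed to the earlier day (the day whose diurnal cycle it
#' terminates), so it aligns with that day's weather and cluster label.
#'
#' @param series cleaned single-tree data.frame.
#' @param morning_end clock time ("HH:MM") closing the morning window.
#' @return data.frame `tree_id`, `date`, `morning_max_mm`, `dcc_mm`.
#'   Days with no reading before `morning_end` get NA morning maxima and are
#'   excluded from DCC (never silently treated as zero).
#' @export
daily_circumference_change <- function(series, morning_end = "11:59") {
  dates <- as.Date(series$timestamp, tz = "UTC")
  udays <- sort(unique(dates))
  if (length(udays) < 2) stop("need at least 2 calendar days of data")
  cutoff <- as.numeric(strsplit(morning_end, ":")[[1]]) %*% c(60, 1)
  mins <- as.POSIXlt(series$timestamp, tz = "UTC")
  mins <- mins$hour * 60 + mins$min
  morning <- mins <= as.numeric(cutoff)
  mm <- vapply(udays, function(d) {
    v <- series$circumference_mm[dates == d & morning]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else max(v)
  }, numeric(1))
  nxt <- match(udays + 1, udays)
  dcc <- mm[nxt] - mm
  dcc[length(dcc)] <- NA  # last day has no following morning maximum
  data.frame(tree_id = series$tree_id[1], date = udays,
             morning_max_mm = mm, dcc_mm = dcc,
             stringsAsFactors = FALSE)
}
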