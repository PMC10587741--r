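#' Stack daily stem-circumference cycles into a day matrix
#'
#' Every complete tree-day (48 half-hourly readings, no missing values)
#' becomes one row, anchored to start at zero by subtracting the day's first
#' reading; absolute circumference would otherwise swamp the cycle shape.
#' Days from all trees are stacked into one matrix.
#'
#' @param series_list list of cleaned single-tree data.frames on the regular
#'   30-min grid.
#' @return object of class `day_matrix`: list with `values` (n x 48 matrix),
#'   `keys` (data.frame `tree_id`, `date`) and `dropped` (count of
#'   incomplete days).
#' @export
build_day_matrix <- function(series_list) {
  if (length(series_list) == 0) stop("empty input: no dendrometer series")
  rows <- list(); keys <- list(); dropped <- 0L
  for (s in series_list) {
    dates <- as.Date(s$timestamp, tz = "UTC")
    for (d in split(seq_len(nrow(s)), dates)) {
      v <- s$circumference_mm[d]
      if (length(v) != 48 || anyNA(v)) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1]] <- v - v[1]
      keys[[length(keys) + 1]] <-
        data.frame(tree_id = s$tree_id[1],
                   date = as.Date(s$timestamp[d[1]], tz = "UTC"))
    }
  }
  if (length(rows) == 0) stop("no complete tree-days in input")
  structure(list(values = do.call(rbind, rows),
                 keys = do.call(rbind, keys),
                 dropped = dropped),
            class = "day_matrix")
}

#' @export
print.day_matrix <- function(x, ...) {
  cat("Day matrix:", nrow(x$values), "tree-days x", ncol(x$values),
      "half-hourly points (", x$dropped, "incomplete days dropped )\n")
  invisible(x)
}

#' Dynamic time warping distance between two sequences
#'
#' Classic DTW with symmetric steps, squared-Euclidean local cost and no
#' warping window; returns the square root of the accumulated cost, so
#' `dtw_distance(a, a) = 0` and the measure is symmetric.
#'
#' @param a,b numeric sequences (finite values).
#' @return nonnegative scalar distance.
#' @export
dtw_distance <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("dtw_distance: inputs must be finite")
  dtw_dist_cpp(as.numeric(a), as.numeric(b))
}
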