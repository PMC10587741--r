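# k-means++ initialization under the DTW metric: subsequent centroids are
# sampled
# with probability proportional to the squared distance to the nearest
# centroid chosen so far, which reliably seeds small well-separated clusters.
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- dtw_assign_cpp(X, X[idx[1], , drop = FALSE])$dist^2
  for (c in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) idx[c] <- sample.int(n, 1)
    else idx[c] <- sample.int(n, 1, prob = d2)
    d_new <- dtw_assign_cpp(X, X[idx[c], , drop = FALSE])$dist^2
    d2 <- pmin(d2, d_new)
  }
  X[idx, , drop = FALSE]
}

#' Cluster daily cycles with DTW k-means
#'
#' k-means over the stacked day matrix using dynamic time warping as the
#' distance and DTW barycenter averaging (DBA) for the centroid update.
#' The best of `n_init` seeded restarts (by inertia, the sum of DTW distances
#' of rows to their assigned centroid) is kept. Cluster labels are 0-based
#' (cluster0 ... cluster{k-1}), following the field convention.
#'
#' @param matrix a [build_day_matrix()] result.
#' @param k number of clusters (2 <= k <= rows).
#' @param seed integer seed; refitting with the same seed reproduces labels.
#' @param n_init number of random restarts.
#' @param max_iter maximum k-means iterations per restart.
#' @param dba_iter barycenter-averaging iterations per centroid update
#'   (capped at 10).
#' @param rel_tol relative inertia improvement below which a restart is
#'   declared converged.
#' @param extra_init optional k x 48 centroid matrix tried as one
#'   additional restart (used by the elbow scan's incremental seeding).
#' @return object of class `cycle_clusters`: `k`, `centroids` (k x 48),
#'   `labels` (0-based integer per row), `inertia`, `seed`, `keys`.
#' @export
cluster_days <- function(matrix, k, seed, n_init = 5, max_iter = 50,
                         dba_iter = 10, rel_tol = 1e-4, extra_init = NULL) {
  X <- matrix$values
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must be in [2, rows]")
  dba_iter <- min(dba_iter, 10L)
  set.seed(seed)
  best <- NULL
  inits <- c(lapply(seq_len(n_init), function(i) .kmeanspp_init(X, k)),
             if (!is.null(extra_init)) list(extra_init))
  for (cen in inits) {
    run <- .dtw_kmeans_run(X, cen, max_iter, dba_iter, rel_tol)
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  structure(list(k = as.integer(k), centroids = best$centroids,
                 labels = best$labels, inertia = best$inertia,
                 seed = seed, keys = matrix$keys),
            class = "cycle_clusters")
}

# one Lloyd-style run: DTW assignment + DBA centroid update until the
# labels stabilise or the inertia improvement falls below rel_tol
.dtw_kmeans_run <- function(X, cen, max_iter, dba_iter, rel_tol) {
  k <- nrow(cen)
  lab <- rep(0L, nrow(X))
  prev_inertia <- Inf
  for (iter in seq_len(max_iter)) {
    a <- dtw_assign_cpp(X, cen)
    new_lab <- a$label
    # re-seed empty clusters with the worst-fitted row
    for (c in seq_len(k)) {
      if (!any(new_lab == c)) {
        far <- which.max(a$dist)
        cen[c, ] <- X[far, ]
        new_lab[far] <- c
      }
    }
    inertia <- sum(a$dist)
    if (iter > 1 && (identical(new_lab, lab) ||
                     prev_inertia - inertia < rel_tol * inertia)) break
    prev_inertia <- inertia
    lab <- new_lab
    for (c in seq_len(k))
      cen[c, ] <- dba_cpp(X[lab == c, , drop = FALSE], cen[c, ],
                          max_iter = dba_iter)
  }
  a <- dtw_assign_cpp(X, cen)
  list(centroids = cen, labels = a$label - 1L, inertia = sum(a$dist))
}

#' @export
print.cycle_clusters <- function(x, ...) {
  cat("DTW k-means cycle clustering: k =", x$k,
      " inertia =", format(x$inertia, digits = 6), "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
plot.cycle_clusters <- function(x, ...) {
  graphics::matplot(t(x$centroids), type = "l", lty = 1,
                    xlab = "half-hour of day", ylab = "circumference offset (mm)",
                    main = "Cluster centroids", ...)
  graphics::legend("topleft", legend = paste0("cluster", seq_len(x$k) - 1),
                   col = seq_len(x$k), lty = 1, bty = "n")
  invisible(x)
}

#' Select the number of clusters by the elbow method
#'
#' Fits [cluster_days()] for each candidate k and returns the k whose point
#' on the inertia curve lies farthest (perpendicular distance) from the chord
#' joining the curve's endpoints. Ties break toward smaller k (parsimony);
#' a flat curve returns the smallest k with a warning. The scan uses lighter
#' restarts than a final fit (`n_init = 2`, `dba_iter = 5` by default): the
#' elbow needs the shape of the inertia curve, not a fully polished optimum
#' at every candidate k.
#'
#' @param matrix a [build_day_matrix()] result.
#' @param k_range integer candidates (at least 3 values).
#' @param seed integer seed, reused for every k.
#' @param n_init,dba_iter restart and barycenter effort per candidate.
#' @param ... passed to [cluster_days()].
#' @return selected k (integer) with attributes `k_range` and `inertia`.
#' @export
elbow_select_k <- function(matrix, k_range = 2:8, seed = 1, n_init = 2,
                           dba_iter = 5, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3) stop("k_range needs at least 3 values")
  inertia <- numeric(length(k_range))
  prev_cen <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    # incremental seeding: also try the previous k's centroids plus the
    # row they fit worst, so each scan point refines the last instead of
    # depending on fresh random starts alone
    extra <- NULL
    if (!is.null(prev_cen) && nrow(prev_cen) == k - 1) {
      far <- which.max(dtw_assign_cpp(matrix$values, prev_cen)$dist)
      extra <- rbind(prev_cen, matrix$values[far, ])
    }
    fit <- cluster_days(matrix, k, seed, n_init = n_init,
                        dba_iter = dba_iter, extra_init = extra, ...)
    inertia[i] <- fit$inertia
    prev_cen <- fit$centroids
  }
  best <- .elbow_pick(k_range, inertia)
  structure(as.integer(best), k_range = k_range, inertia = inertia)
}

# Chord rule on the normalized inertia curve. Axes are rescaled to [0, 1]
# before measuring perpendicular distances, so the pick does not depend on
# the units of the inertia. Two degenerate shapes have no elbow and fall
# back to the smallest k with a warning: an essentially flat curve (total
# relative drop below flat_tol, e.g. the true structure is already resolved
# at the smallest candidate) and an essentially linear decay (all points on
# the chord).
.elbow_pick <- function(k_range, inertia, flat_tol = 0.15, line_tol = 0.02) {
  y1 <- inertia[1]; y2 <- inertia[length(inertia)]
  if (!is.finite(y1) || y1 <= 0 || (y1 - y2) < flat_tol * abs(y1)) {
    warning("no pronounced elbow (flat inertia curve); returning smallest k")
    return(k_range[1])
  }
  kx <- (k_range - k_range[1]) / (k_range[length(k_range)] - k_range[1])
  iy <- (inertia - y2) / (y1 - y2)
  # chord runs from (0, 1) to (1, 0); distance of (x, y) to it
  d <- (1 - kx - iy) / sqrt(2)
  if (max(d) < line_tol) {
    warning("no pronounced elbow (linear inertia decay); returning smallest k")
    return(k_range[1])
  }
  k_range[which.max(d)]  # which.max takes the first (smallest k) on ties
}

#' Assign growing / non-growing groups to clusters
#'
#' A cluster's net change is the mean, over its member rows, of the day's
#' last minus first (anchored, so first = 0) circumference value. Clusters
#' with strictly positive net change form the growing group (GC); the rest
#' the non-growing group (NGC). Net changes smaller than `tol` — below the
#' resolution of a band dendrometer — count as stable, so a cluster whose
#' mean net change is zero up to sampling noise is non-growing, not a coin
#' flip on the noise sign.
#'
#' @param model a [cluster_days()] fit.
#' @param matrix the day matrix the model was fitted on.
#' @param tol stable-cluster tolerance in mm/day (default 0.005, well
#'   below any real daily increment a band dendrometer resolves).
#' @return data.frame `cluster`, `n`, `net_change_mm`, `group`.
#' @export
assign_groups <- function(model, matrix, tol = 5e-3) {
  X <- matrix$values
  if (length(model$labels) != nrow(X))
    stop("model was not fitted on this matrix")
  net_row <- X[, ncol(X)] - X[, 1]
  out <- lapply(seq_len(model$k) - 1L, function(c) {
    idx <- model$labels == c
    if (!any(idx)) stop("cluster ", c, " is empty")
    nc <- mean(net_row[idx])
    data.frame(cluster = c, n = sum(idx), net_change_mm = nc,
               group = if (nc > tol) "GC" else "NGC")
  })
  do.call(rbind, out)
}

#' Dunn's post-hoc test (rank-based pairwise z) with tie correction
#'
#' @param values numeric vector.
#' @param groups factor/vector of group labels.
#' @param p_adjust multiplicity correction for the pairwise p-values.
#' @return data.frame `g1`, `g2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[i] + 1 / ns[j]))
    z <- (rbar[i] - rbar[j]) / se
    c(z = unname(z), p = unname(2 * stats::pnorm(-abs(z))))
  })
  out <- data.frame(g1 = pairs[1, ], g2 = pairs[2, ],
                    z = res["z", ], p = res["p", ])
  out$p_adj <- pmin(1, stats::p.adjust(out$p, method = p_adjust))
  rownames(out) <- NULL
  out
}

# Compact letter display: letters are the maximal cliques of the
# "not significantly different" graph (exhaustive; fine for k <= 12).
.compact_letters <- function(levels, pairs, alpha = 0.05) {
  k <- length(levels)
  if (k > 12) stop("compact letter display supported for k <= 12")
  nsd <- diag(TRUE, k)
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$g1[r], levels); j <- match(pairs$g2[r], levels)
    if (pairs$p_adj[r] >= alpha) nsd[i, j] <- nsd[j, i] <- TRUE
  }
  cliques <- list()
  for (s in seq_len(2^k - 1)) {
    members <- which(bitwAnd(s, 2^(seq_len(k) - 1)) > 0)
    if (all(nsd[members, members])) cliques[[length(cliques) + 1]] <- members
  }
  # keep maximal cliques only
  maximal <- Filter(function(m) {
    !any(vapply(cliques, function(o)
      length(o) > length(m) && all(m %in% o), logical(1)))
  }, cliques)
  maximal <- maximal[order(vapply(maximal, min, numeric(1)))]
  lets <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(maximal, function(m) i %in% m, logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(lets, levels)
}

#' Test cluster-wise differences in daily climate
#'
#' Kruskal-Wallis test per climate variable across clusters, followed by
#' Dunn's pairwise post-hoc z tests with Bonferroni adjustment, summarised
#' with a compact letter display (clusters sharing a letter do not differ at
#' `alpha`).
#'
#' @param labels cluster label per day (aligned with `climate` rows).
#' @param climate data.frame with columns `tmin_c`, `tmax_c`, `prec_mm`
#'   (one row per label).
#' @param alpha significance level for the letter display.
#' @return named list (one element per variable) of lists with `kw_stat`,
#'   `kw_p`, `dunn` (pairwise table) and `letters`.
#' @export
cluster_climate_tests <- function(labels, climate, alpha = 0.05) {
  if (length(labels) != nrow(climate))
    stop("labels and climate must be aligned")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 clusters with >= 2 members each")
  vars <- c("tmin_c", "tmax_c", "prec_mm")
  out <- lapply(vars, function(v) {
    x <- climate[[v]]
    if (length(unique(x)) == 1)
      return(list(kw_stat = NA_real_, kw_p = NA_real_, dunn = NULL,
                  letters = NULL, note = "all values tied; test undefined"))
    kw <- stats::kruskal.test(x, factor(labels))
    dn <- dunn_test(x, labels)
    lv <- levels(factor(labels))
    list(kw_stat = unname(kw$statistic), kw_p = kw$p.value, dunn = dn,
         letters = .compact_letters(lv, dn, alpha))
  })
  stats::setNames(out, vars)
}
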