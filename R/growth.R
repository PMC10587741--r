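#' Monthly aggregated circumference change (GRO)
#'
#' Sums DCC within each calendar month per tree (days without a valid DCC
#' are excluded, not imputed as zero) and averages across the trees
#' contributing to that month.
#'
#' @param dcc_list list of [daily_circumference_change()] data.frames.
#' @return data.frame `month` ("YYYY-MM"), `gro_mm` (site mean of per-tree
#'   monthly sums), `n_trees`.
#' @export
monthly_growth <- function(dcc_list) {
  if (length(dcc_list) == 0) stop("empty input: no DCC series")
  all <- do.call(rbind, dcc_list)
  all <- all[!is.na(all$dcc_mm), , drop = FALSE]
  all$month <- .year_month(all$date)
  per_tree <- stats::aggregate(dcc_mm ~ tree_id + month, data = all, FUN = sum)
  site <- stats::aggregate(dcc_mm ~ month, data = per_tree, FUN = mean)
  ntr <- stats::aggregate(tree_id ~ month, data = per_tree,
                          FUN = function(x) length(unique(x)))
  out <- data.frame(month = site$month, gro_mm = site$dcc_mm,
                    n_trees = ntr$tree_id[match(site$month, ntr$month)])
  out[order(out$month), ]
}

#' Correlate monthly cluster counts with monthly growth
#'
#' Pearson correlation (two-sided p) between monthly growth and the monthly
#' count of each cluster class and of the GC / NGC groups.
#'
#' @param counts data.frame with a `month` column and one numeric count
#'   column per term (clusters and/or groups).
#' @param gro a [monthly_growth()] data.frame.
#' @return data.frame `term`, `r`, `p`, `n`.
#' @export
correlate_counts_growth <- function(counts, gro) {
  m <- merge(counts, gro[, c("month", "gro_mm")], by = "month")
  if (nrow(m) < 12) stop("need >= 12 paired months")
  terms <- setdiff(names(counts), "month")
  out <- lapply(terms, function(t) {
    x <- m[[t]]
    if (stats::sd(x) == 0 || stats::sd(m$gro_mm) == 0) {
      warning("zero variance for term ", t, "; correlation undefined")
      return(data.frame(term = t, r = NA_real_, p = NA_real_, n = nrow(m)))
    }
    ct <- stats::cor.test(x, m$gro_mm, method = "pearson")
    data.frame(term = t, r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
  })
  do.call(rbind, out)
}

#' Fit the linear growth model (GRO on growing-cluster days)
#'
#' Ordinary least squares of monthly growth on the monthly count of
#' growing-cluster (GC) days, with intercept. Counts for a single cluster or
#' the NGC group can be passed instead, giving the other calibrations of the
#' same interface.
#'
#' @param gro a [monthly_growth()] data.frame (or numeric vector).
#' @param gc_counts data.frame `month`, `count` (or numeric vector aligned
#'   with `gro`).
#' @return object of class `growth_model` wrapping the `lm` fit, with
#'   `intercept` (mm/month) and `slope` (mm per GC-day).
#' @export
fit_growth_model <- function(gro, gc_counts) {
  if (is.data.frame(gro)) {
    m <- merge(gc_counts, gro[, c("month", "gro_mm")], by = "month")
    y <- m$gro_mm; x <- m$count; span <- range(m$month)
  } else {
    y <- as.numeric(gro); x <- as.numeric(gc_counts); span <- NULL
    m <- data.frame(count = x, gro_mm = y)
  }
  if (length(y) < 12) stop("need >= 12 months to fit the growth model")
  if (stats::sd(x) == 0) stop("constant counts: design is rank deficient")
  fit <- stats::lm(gro_mm ~ count, data = m)
  structure(list(fit = fit,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 span = span, data = m),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf(
    "Linear growth model: GRO = %.4f + %.4f x GC-days (mm/month, n = %d)\n",
    x$intercept, x$slope, nrow(x$data)))
  invisible(x)
}

#' @export
coef.growth_model <- function(object, ...) stats::coef(object$fit)

#' @export
predict.growth_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit))
  if (is.numeric(newdata)) newdata <- data.frame(count = newdata)
  stats::predict(object$fit, newdata = newdata)
}

#' @export
residuals.growth_model <- function(object, ...) stats::residuals(object$fit)

#' @export
summary.growth_model <- function(object, ...) summary(object$fit)

#' Blocked 10-fold cross-validation of the growth model
#'
#' Months are kept in time order and cut into `folds` contiguous blocks
#' (remainder months spread one per block from the first). Each fold trains
#' on the other blocks and evaluates the held-out block: R-squared
#' (1 - SS_res / SS_tot), variance explained (1 - var(resid) / var(obs)) and
#' RMSE.
#'
#' @param gro a [monthly_growth()] data.frame.
#' @param gc_counts data.frame `month`, `count`.
#' @param folds number of contiguous blocks (default 10).
#' @return object of class `cv_report`: per-fold data.frame and
#'   mean +/- SD summary.
#' @export
blocked_cv <- function(gro, gc_counts, folds = 10) {
  m <- merge(gc_counts, gro[, c("month", "gro_mm")], by = "month")
  m <- m[order(m$month), ]
  n <- nrow(m)
  if (n < 20) stop("need >= 20 months for blocked cross-validation")
  if (folds > n) stop("more folds than months")
  base <- n %/% folds; rem <- n %% folds
  sizes <- rep(base, folds) + c(rep(1, rem), rep(0, folds - rem))
  fold_id <- rep(seq_len(folds), times = sizes)
  res <- lapply(seq_len(folds), function(f) {
    tr <- m[fold_id != f, ]; te <- m[fold_id == f, ]
    fit <- stats::lm(gro_mm ~ count, data = tr)
    pred <- stats::predict(fit, newdata = te)
    resid <- te$gro_mm - pred
    ss_tot <- sum((te$gro_mm - mean(te$gro_mm))^2)
    r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
    ve <- if (ss_tot > 0) 1 - stats::var(resid) / stats::var(te$gro_mm)
          else NA_real_
    data.frame(fold = f, n = nrow(te), r2 = r2, ve = ve,
               rmse = sqrt(mean(resid^2)))
  })
  per_fold <- do.call(rbind, res)
  structure(list(
    per_fold = per_fold, folds = folds,
    summary = data.frame(
      metric = c("r2", "ve", "rmse"),
      mean = c(mean(per_fold$r2), mean(per_fold$ve), mean(per_fold$rmse)),
      sd = c(stats::sd(per_fold$r2), stats::sd(per_fold$ve),
             stats::sd(per_fold$rmse)))),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d-fold blocked CV: R2 = %.2f +/- %.2f, VE = %.2f +/- %.2f, RMSE = %.2f +/- %.2f\n",
              x$folds, s$mean[1], s$sd[1], s$mean[2], s$sd[2],
              s$mean[3], s$sd[3]))
  invisible(x)
}

#' Project monthly growth for a future window
#'
#' Averages a scenario window's monthly GC counts by calendar month, predicts
#' monthly growth with the fitted model, and expresses the change against
#' the observed baseline: per-month percent change 100 * (pred - obs) / obs
#' and a total percent change over January-December weighted by the observed
#' monthly growth (equivalently, the percent change of the annual sum).
#'
#' @param model a [fit_growth_model()] fit.
#' @param future_counts data.frame `month` ("YYYY-MM"), `count` covering the
#'   scenario window.
#' @param obs_gro observed [monthly_growth()] table used as baseline.
#' @return data.frame with rows Jan..Dec: `month_num`, `pred_gro_mm`,
#'   `obs_gro_mm`, `pct_change`; attribute `total_pct_change`.
#' @export
project_growth <- function(model, future_counts, obs_gro) {
  mo_f <- as.integer(substr(future_counts$month, 6, 7))
  pred_counts <- tapply(future_counts$count, mo_f, mean)
  mo_o <- as.integer(substr(obs_gro$month, 6, 7))
  obs_m <- tapply(obs_gro$gro_mm, mo_o, mean)
  months <- 1:12
  pred <- predict(model, as.numeric(pred_counts[as.character(months)]))
  obs <- as.numeric(obs_m[as.character(months)])
  pct <- ifelse(obs == 0, NA_real_, 100 * (pred - obs) / obs)
  if (any(obs == 0, na.rm = TRUE))
    warning("months with zero observed growth: percent change undefined")
  out <- data.frame(month_num = months, pred_gro_mm = as.numeric(pred),
                    obs_gro_mm = obs, pct_change = pct)
  attr(out, "total_pct_change") <-
    100 * (sum(pred) - sum(obs)) / sum(obs)
  out
}

#' Mean and population SD of per-scenario day shifts
#'
#' Aggregates the per-scenario onset/cessation day shifts of one period into
#' mean +/- population (n-divisor) standard deviation, rounded to whole days.
#'
#' @param deltas numeric vector of per-scenario day shifts (>= 2 values).
#' @return named numeric `c(mean, sd)` in integer days.
#' @export
delta_day_stats <- function(deltas) {
  if (length(deltas) < 2) stop("need >= 2 scenarios")
  m <- mean(deltas)
  s <- sqrt(mean((deltas - m)^2))
  c(mean = round(m), sd = round(s))
}
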