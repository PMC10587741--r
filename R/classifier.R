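#' F1 score from confusion counts
#'
#' F1 = tp / (tp + (fp + fn) / 2), the harmonic mean of precision and recall.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts
#'   (nonnegative; tp + fp + fn > 0). Vectorised.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(tp < 0 | fp < 0 | fn < 0)) stop("counts must be nonnegative")
  if (any(tp + fp + fn == 0)) stop("F1 undefined when all counts are zero")
  tp / (tp + (fp + fn) / 2)
}

#' Per-class classification report
#'
#' One-vs-rest confusion counts per class with precision, recall and F1,
#' overall accuracy, and macro (unweighted) and weighted (support-weighted)
#' averages — the layout of a standard multi-class performance table.
#' Accuracy equals the support-weighted mean recall (micro-average recall).
#'
#' @param truth,pred equal-length label vectors.
#' @return object of class `classification_report`: `per_class`
#'   (data.frame class/precision/recall/f1/support/tp/fp/fn), `accuracy`,
#'   `macro` and `weighted` (precision/recall/f1), `n`.
#' @export
classification_report <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred must be aligned")
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(c(truth, pred)))
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_  # class absent from truth
    f1 <- if (tp + fp + fn > 0) f1_score(tp, fp, fn) else NA_real_
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = tp + fn, tp = tp, fp = fp, fn = fn)
  })
  per <- do.call(rbind, per)
  n <- length(truth)
  # zero-support classes (predicted but absent from the truth) carry zero
  # weight and are excluded from the support-weighted averages
  idx <- per$support > 0
  w <- per$support[idx] / n
  wavg <- function(m) sum(m[idx] * w)
  structure(list(
    per_class = per,
    accuracy = sum(truth == pred) / n,
    macro = c(precision = mean(per$precision), recall = mean(per$recall),
              f1 = mean(per$f1)),
    weighted = c(precision = wavg(per$precision),
                 recall = wavg(per$recall),
                 f1 = wavg(per$f1)),
    n = n), class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  p <- x$per_class
  cat(sprintf("%-12s %9s %9s %9s %9s\n", "", "precision", "recall",
              "f1-score", "support"))
  for (i in seq_len(nrow(p)))
    cat(sprintf("%-12s %9.*f %9.*f %9.*f %9d\n", p$class[i],
                digits, p$precision[i], digits, p$recall[i],
                digits, p$f1[i], p$support[i]))
  cat(sprintf("%-12s %29.*f %9d\n", "accuracy", digits, x$accuracy, x$n))
  cat(sprintf("%-12s %9.*f %9.*f %9.*f %9d\n", "macro avg",
              digits, x$macro["precision"], digits, x$macro["recall"],
              digits, x$macro["f1"], x$n))
  cat(sprintf("%-12s %9.*f %9.*f %9.*f %9d\n", "weighted avg",
              digits, x$weighted["precision"], digits, x$weighted["recall"],
              digits, x$weighted["f1"], x$n))
  invisible(x)
}

# month as a one-of-twelve categorical; numeric coding would impose an
# artificial December -> January distance
.classifier_frame <- function(features) {
  need <- c("tmin_c", "tmax_c", "prec_mm", "month")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  data.frame(tmin_c = features$tmin_c, tmax_c = features$tmax_c,
             prec_mm = features$prec_mm,
             month = factor(features$month, levels = 1:12))
}

#' Train a random-forest climate-to-cluster classifier
#'
#' Maps daily climate (Tmin, Tmax, Prec and calendar month as a categorical
#' predictor) to the daily cycle-cluster class. The data are split into a
#' seeded, stratified random 60/40 train/test partition; performance reports
#' are computed on both parts.
#'
#' @param features data.frame `tmin_c`, `tmax_c`, `prec_mm`, `month` (1-12).
#' @param labels cluster class per row.
#' @param seed integer seed (split and forest).
#' @param train_frac training fraction (default 0.6).
#' @param num_trees forest size.
#' @return object of class `cluster_rf`: fitted forest, split indices, seed,
#'   train/test [classification_report()]s.
#' @export
train_classifier <- function(features, labels, seed, train_frac = 0.6,
                             num_trees = 500) {
  df <- .classifier_frame(features)
  labels <- factor(labels)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 5))
    stop("need >= 2 classes with >= 5 rows each")
  set.seed(seed)
  train_idx <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1, round(length(idx) * train_frac)))
  }))
  train_idx <- sort(train_idx)
  small <- names(tab)[tapply(seq_along(labels) %in% train_idx, labels, sum) < 2]
  if (length(small) > 0)
    warning("classes with < 2 training rows retained: ",
            paste(small, collapse = ", "))
  train <- cbind(df[train_idx, , drop = FALSE],
                 cluster = labels[train_idx])
  fit <- ranger::ranger(cluster ~ ., data = train, num.trees = num_trees,
                        seed = seed, num.threads = 1)
  pred_train <- predict(fit, data = df[train_idx, , drop = FALSE])$predictions
  test_idx <- setdiff(seq_along(labels), train_idx)
  pred_test <- predict(fit, data = df[test_idx, , drop = FALSE])$predictions
  structure(list(
    model = fit, seed = seed, train_frac = train_frac,
    train_idx = train_idx, test_idx = test_idx,
    levels = levels(labels),
    report_train = classification_report(labels[train_idx], pred_train),
    report_test = classification_report(labels[test_idx], pred_test)),
    class = "cluster_rf")
}

#' @export
print.cluster_rf <- function(x, ...) {
  cat("Random-forest cycle-cluster classifier (",
      length(x$train_idx), "train /", length(x$test_idx), "test )\n")
  cat(sprintf("train accuracy %.2f, test accuracy %.2f\n",
              x$report_train$accuracy, x$report_test$accuracy))
  invisible(x)
}

#' Predict daily cycle clusters from a climate series
#'
#' Applies a trained classifier to a daily climate series and tabulates
#' monthly cluster counts. Days with missing climate are excluded from the
#' counts with a warning, never silently imputed.
#'
#' @param model a [train_classifier()] fit.
#' @param climate data.frame `date`, `tmin_c`, `tmax_c`, `prec_mm`.
#' @return list: `daily` (data.frame `date`, `cluster`) and
#'   `monthly_counts` (data.frame `month` + one column per cluster class).
#' @export
predict_clusters <- function(model, climate) {
  need <- c("date", "tmin_c", "tmax_c", "prec_mm")
  if (!all(need %in% names(climate)))
    stop("climate must have columns: ", paste(need, collapse = ", "))
  ok <- stats::complete.cases(climate[, need])
  if (!all(ok))
    warning(sum(!ok), " days with missing climate excluded from predictions")
  cl <- climate[ok, , drop = FALSE]
  feats <- .classifier_frame(
    data.frame(tmin_c = cl$tmin_c, tmax_c = cl$tmax_c, prec_mm = cl$prec_mm,
               month = as.integer(format(cl$date, "%m"))))
  pred <- as.character(predict(model$model, data = feats)$predictions)
  daily <- data.frame(date = cl$date, cluster = pred)
  ym <- .year_month(daily$date)
  tab <- table(month = ym, cluster = factor(pred, levels = model$levels))
  counts <- as.data.frame.matrix(tab)
  counts <- cbind(month = rownames(counts), counts, row.names = NULL)
  list(daily = daily, monthly_counts = counts)
}
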