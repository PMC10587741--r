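#' Kling-Gupta efficiency
#'
#' KGE = 1 - sqrt((r - 1)^2 + (beta - 1)^2 + (gamma - 1)^2), where r is the
#' Pearson correlation between simulated and observed series, beta the ratio
#' of means (mu_s / mu_o) and gamma the ratio of coefficients of variation
#' ((sigma_s / mu_s) / (sigma_o / mu_o)). KGE = 1 only for a perfect match;
#' values above 0.5 are conventionally read as good skill.
#'
#' @param sim,obs equal-length numeric series (n >= 3).
#' @return object of class `kge`: list `r`, `beta`, `gamma`, `kge`.
#' @export
kge <- function(sim, obs) {
  if (length(sim) != length(obs) || length(obs) < 3)
    stop("sim and obs must have equal length >= 3")
  mu_o <- mean(obs); sd_o <- stats::sd(obs)
  if (mu_o == 0) stop("observed mean is zero; KGE undefined")
  if (sd_o == 0) stop("observed SD is zero; KGE undefined")
  mu_s <- mean(sim); sd_s <- stats::sd(sim)
  r <- stats::cor(sim, obs)
  beta <- mu_s / mu_o
  gamma <- (sd_s / mu_s) / (sd_o / mu_o)
  structure(list(r = r, beta = beta, gamma = gamma,
                 kge = 1 - sqrt((r - 1)^2 + (beta - 1)^2 + (gamma - 1)^2)),
            class = "kge")
}

#' @export
print.kge <- function(x, ...) {
  cat(sprintf("KGE = %.3f (r = %.3f, beta = %.3f, gamma = %.3f)\n",
              x$kge, x$r, x$beta, x$gamma))
  invisible(x)
}

#' Rank candidate climate models by Kling-Gupta efficiency
#'
#' Computes per-variable KGE of each candidate's monthly series against the
#' observed monthly series over their common months and ranks candidates by
#' the unweighted mean of the three scores. Variables with KGE <= 0.5 are
#' flagged as poor skill.
#'
#' @param candidates named list of monthly data.frames
#'   (`date`, `tmin_c`, `tmax_c`, `prec_mm`).
#' @param obs observed monthly data.frame, same schema.
#' @param min_overlap smallest acceptable overlap in months.
#' @return list with `table` (one row per candidate: per-variable KGE,
#'   `mean_kge`, `flagged`), and `best` (name of the top candidate).
#' @export
rank_gcms <- function(candidates, obs, min_overlap = 24) {
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("candidates must be a named list")
  vars <- c("tmin_c", "tmax_c", "prec_mm")
  rows <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    common <- intersect(as.character(cand$date), as.character(obs$date))
    if (length(common) < min_overlap)
      stop("candidate ", nm, ": overlap of ", length(common),
           " months is below ", min_overlap)
    ci <- match(common, as.character(cand$date))
    oi <- match(common, as.character(obs$date))
    ks <- vapply(vars, function(v) kge(cand[[v]][ci], obs[[v]][oi])$kge,
                 numeric(1))
    data.frame(model = nm, kge_tmin = ks[1], kge_tmax = ks[2],
               kge_prec = ks[3], mean_kge = mean(ks),
               flagged = paste(vars[ks <= 0.5], collapse = ","),
               n_months = length(common))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$mean_kge), ]
  rownames(tab) <- NULL
  list(table = tab, best = tab$model[1])
}

# day-of-year harmonic covariates (two harmonics)
.doy_harmonics <- function(date) {
  doy <- as.POSIXlt(date)$yday + 1
  w <- 2 * pi * doy / 365.25
  data.frame(sin1 = sin(w), cos1 = cos(w), sin2 = sin(2 * w), cos2 = cos(2 * w))
}

.downscale_features <- function(date, sim_value, covariates) {
  f <- data.frame(sim = sim_value)
  if (covariates == "sim+doy") f <- cbind(f, .doy_harmonics(date))
  f
}

#' Downscale a daily temperature series with a random forest
#'
#' A regression forest is trained on the calibration overlap to map the
#' simulated daily value (plus day-of-year harmonics, by default) to the
#' observed station value, then applied to the scenario series.
#'
#' @param sim data.frame `date`, `value`: simulated series over the
#'   calibration period.
#' @param obs data.frame `date`, `value`: observed station series.
#' @param scenario data.frame `date`, `value`: simulated future series.
#' @param seed integer seed (forest is deterministic given the seed).
#' @param covariates `"sim+doy"` (default) or `"sim-only"`.
#' @param num_trees forest size.
#' @return data.frame `date`, `value` of corrected scenario values.
#' @export
downscale_temperature <- function(sim, obs, scenario, seed,
                                  covariates = c("sim+doy", "sim-only"),
                                  num_trees = 500) {
  covariates <- match.arg(covariates)
  common <- intersect(as.character(sim$date), as.character(obs$date))
  if (length(common) < 365)
    stop("calibration overlap shorter than one year")
  si <- match(common, as.character(sim$date))
  oi <- match(common, as.character(obs$date))
  train <- .downscale_features(as.Date(common), sim$value[si], covariates)
  train$y <- obs$value[oi]
  fit <- ranger::ranger(y ~ ., data = train, num.trees = num_trees,
                        seed = seed, num.threads = 1)
  newdata <- .downscale_features(scenario$date, scenario$value, covariates)
  data.frame(date = scenario$date,
             value = predict(fit, data = newdata)$predictions)
}

#' Downscale daily precipitation with the two-step random forest
#'
#' Step one trains a classification forest separating wet from dry station
#' days; step two trains a regression forest for the rainfall amount on
#' observed-wet days only. A scenario day classified dry gets exactly 0 mm;
#' wet days get the (nonnegative) predicted amount.
#'
#' @param sim,obs,scenario data.frames `date`, `value` (mm/day) as in
#'   [downscale_temperature()].
#' @param wet_threshold wet-day threshold in mm.
#' @param seed integer seed.
#' @param covariates `"sim+doy"` or `"sim-only"`.
#' @param num_trees forest size.
#' @return data.frame `date`, `value` with value >= 0 and exact zeros on
#'   predicted-dry days.
#' @export
downscale_precipitation <- function(sim, obs, scenario, wet_threshold = 0.1,
                                    seed = 1,
                                    covariates = c("sim+doy", "sim-only"),
                                    num_trees = 500) {
  covariates <- match.arg(covariates)
  common <- intersect(as.character(sim$date), as.character(obs$date))
  if (length(common) < 60) stop("calibration overlap too short")
  si <- match(common, as.character(sim$date))
  oi <- match(common, as.character(obs$date))
  wet <- obs$value[oi] >= wet_threshold
  if (!any(wet) || all(wet))
    stop("calibration overlap must contain both wet and dry days")
  feats <- .downscale_features(as.Date(common), sim$value[si], covariates)
  feats$sim_wet <- as.numeric(sim$value[si] >= wet_threshold)
  occ_train <- cbind(feats, wet = factor(wet, levels = c(FALSE, TRUE)))
  occ <- ranger::ranger(wet ~ ., data = occ_train, num.trees = num_trees,
                        seed = seed, num.threads = 1)
  amt_train <- cbind(feats[wet, , drop = FALSE], y = obs$value[oi][wet])
  amt <- ranger::ranger(y ~ ., data = amt_train, num.trees = num_trees,
                        seed = seed + 1, num.threads = 1)
  newdata <- .downscale_features(scenario$date, scenario$value, covariates)
  newdata$sim_wet <- as.numeric(scenario$value >= wet_threshold)
  is_wet <- predict(occ, data = newdata)$predictions == "TRUE"
  out <- numeric(nrow(scenario))
  if (any(is_wet))
    out[is_wet] <- pmax(0, predict(amt, data = newdata[is_wet, ,
                                                       drop = FALSE])$predictions)
  data.frame(date = scenario$date, value = out)
}

#' Extract the mid- and late-century analysis windows
#'
#' Slices a daily scenario series to the exact calendar windows
#' 2048-01-01..2053-12-31 ("2050s") and 2095-01-01..2100-12-31 ("2100s"),
#' six years each.
#'
#' @param daily data.frame with a `date` column covering both windows.
#' @param periods named list of `c(start, end)` date strings.
#' @return named list of data.frame slices.
#' @export
extract_periods <- function(daily,
                            periods = list(
                              "2050s" = c("2048-01-01", "2053-12-31"),
                              "2100s" = c("2095-01-01", "2100-12-31"))) {
  out <- lapply(names(periods), function(nm) {
    w <- as.Date(periods[[nm]])
    span <- seq(w[1], w[2], by = "day")
    if (!all(span %in% daily$date))
      stop("scenario series does not cover the ", nm, " window")
    daily[daily$date >= w[1] & daily$date <= w[2], , drop = FALSE]
  })
  stats::setNames(out, names(periods))
}
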