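#' Fit a smooth cumulative-growth curve
#'
#' Penalized-spline smooth (GAM, cubic regression basis, automatic smoothness
#' selection) of cumulative growth over day of year, evaluated on every DOY
#' of the grid. The daily growth rate is the first derivative of the smooth,
#' obtained from finite differences of the linear-predictor matrix (the
#' standard mgcv derivative construction).
#'
#' @param doy day-of-year values of the input points.
#' @param cumulative cumulative growth (mm) at those days.
#' @param basis_dim spline basis dimension (reduced automatically when few
#'   points are supplied).
#' @param grid_max last DOY of the evaluation grid (365, or 366 for leap
#'   coverage).
#' @return object of class `cumulative_curve`: `doy`, `cumulative` (fitted),
#'   `rate` (mm/day), the `gam` fit and the input `points`. A non-monotone
#'   smooth is recorded in the `monotone` field, not forced monotone.
#' @export
fit_cumulative_curve <- function(doy, cumulative, basis_dim = 12,
                                 grid_max = 365) {
  if (length(doy) < 8) stop("need >= 8 points spanning the year")
  k <- min(basis_dim, length(doy) - 2)
  dat <- data.frame(doy = doy, y = cumulative)
  fit <- mgcv::gam(y ~ s(doy, k = k, bs = "cr"), data = dat)
  grid <- seq_len(grid_max)
  fitted <- as.numeric(predict(fit, newdata = data.frame(doy = grid)))
  eps <- 1e-3
  X1 <- predict(fit, newdata = data.frame(doy = grid + eps), type = "lpmatrix")
  X0 <- predict(fit, newdata = data.frame(doy = grid - eps), type = "lpmatrix")
  rate <- as.numeric((X1 - X0) %*% stats::coef(fit)) / (2 * eps)
  structure(list(doy = grid, cumulative = fitted, rate = rate,
                 gam = fit, points = dat,
                 monotone = !any(diff(fitted) < -1e-9)),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("Cumulative growth curve: %d points, total %.3f mm%s\n",
              nrow(x$points), x$cumulative[length(x$cumulative)],
              if (x$monotone) "" else " (non-monotone smooth)"))
  invisible(x)
}

#' @export
plot.cumulative_curve <- function(x, ...) {
  graphics::plot(x$doy, x$cumulative, type = "l",
                 xlab = "day of year", ylab = "cumulative growth (mm)", ...)
  graphics::points(x$points$doy, x$points$y, pch = 16, cex = 0.6)
  invisible(x)
}

#' Statistical growing-season dates from a cumulative curve
#'
#' Season onset (SOS) is the first DOY at which cumulative growth reaches
#' `lower` (default 2.5%) of the annual total; cessation (EOS) the first DOY
#' reaching `upper` (97.5%); season length GS = EOS - SOS. The thresholds
#' are relative, so the dates are invariant to positive rescaling.
#'
#' @param curve a [fit_cumulative_curve()] result.
#' @param lower,upper relative thresholds.
#' @return object of class `season_dates`: list `sos`, `eos`, `gs`.
#' @export
season_dates <- function(curve, lower = 0.025, upper = 0.975) {
  cum <- curve$cumulative
  total <- cum[length(cum)]
  if (!is.finite(total) || total <= 0)
    stop("non-positive total cumulative growth; season dates undefined")
  sos <- curve$doy[which(cum >= lower * total)[1]]
  eos <- curve$doy[which(cum >= upper * total)[1]]
  structure(list(sos = sos, eos = eos, gs = eos - sos),
            class = "season_dates")
}

#' @export
print.season_dates <- function(x, ...) {
  cat(sprintf("SOS = DOY %d, EOS = DOY %d, GS = %d days\n",
              x$sos, x$eos, x$gs))
  invisible(x)
}

#' Compare observed and scenario growing seasons
#'
#' Day shifts are future minus observed, so positive means later (SOS/EOS)
#' or longer (GS); Delta GS = Delta EOS - Delta SOS by construction.
#'
#' @param observed,scenario [season_dates()] objects.
#' @return named numeric `c(dsos, deos, dgs)` in days.
#' @export
compare_seasons <- function(observed, scenario) {
  c(dsos = scenario$sos - observed$sos,
    deos = scenario$eos - observed$eos,
    dgs = scenario$gs - observed$gs)
}

#' Observed cumulative-growth points by day of year
#'
#' Cross-tree, cross-year mean DCC per DOY, accumulated over the year.
#' Feb 29 readings are merged into DOY 60.
#'
#' @param dcc_list list of [daily_circumference_change()] data.frames.
#' @return data.frame `doy`, `cumulative_mm` (one row per observed DOY).
#' @export
observed_cumulative_points <- function(dcc_list) {
  all <- do.call(rbind, dcc_list)
  all <- all[!is.na(all$dcc_mm), ]
  doy <- as.POSIXlt(all$date)$yday + 1
  yr <- as.integer(format(all$date, "%Y"))
  is_leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  shift <- is_leap & format(all$date, "%m-%d") >= "03-01"
  doy[shift] <- doy[shift] - 1  # merge Feb 29 into DOY 60, realign the rest
  rate <- tapply(all$dcc_mm, doy, mean)
  d <- as.integer(names(rate))
  data.frame(doy = d, cumulative_mm = cumsum(as.numeric(rate)))
}

#' Cumulative points from predicted monthly growth
#'
#' Places the window-averaged predicted monthly growth as cumulative values
#' at month-end days of year (plus a zero anchor at DOY 1), the input for
#' smoothing a daily future curve.
#'
#' @param monthly_gro numeric vector of 12 monthly growth values (Jan..Dec).
#' @return data.frame `doy`, `cumulative_mm` (13 points).
#' @export
future_cumulative_points <- function(monthly_gro) {
  stopifnot(length(monthly_gro) == 12)
  ends <- cumsum(.months_days(leap = FALSE))
  data.frame(doy = c(1, ends),
             cumulative_mm = c(0, cumsum(monthly_gro)))
}
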