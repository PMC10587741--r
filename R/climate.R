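#' Read a daily station-climate CSV
#'
#' Expects columns `date`, `tmin_c`, `tmax_c`, `prec_mm` (optionally
#' `pet_mm`, `mi_mm`).
#'
#' @param path path to the CSV.
#' @return data.frame with `date` as Date.
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin_c", "tmax_c", "prec_mm")
  if (!all(need %in% names(df)))
    stop("climate CSV must have columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  df
}

#' Extraterrestrial radiation (FAO-56)
#'
#' Daily extraterrestrial radiation from day-of-year and latitude
#' (solar constant 0.0820 MJ m-2 min-1; FAO-56 declination and sunset-hour
#' angle approximations).
#'
#' @param doy day of year (1-366).
#' @param latitude site latitude in decimal degrees.
#' @return radiation in MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Hargreaves-Samani potential evapotranspiration
#'
#' PET = 0.0023 * Ra * (Tmean + 17.8) * sqrt(Tmax - Tmin), with Ra the
#' FAO-56 extraterrestrial radiation converted to its evaporation
#' equivalent (x 0.408 mm per MJ m-2). Negative values are clipped to zero.
#'
#' @param date Date vector (or day-of-year integers).
#' @param latitude site latitude in decimal degrees (|lat| <= 66).
#' @param tmin,tmax daily minimum/maximum temperature in deg C.
#' @return PET in mm/day.
#' @export
hargreaves_pet <- function(date, latitude, tmin, tmax) {
  if (abs(latitude) > 66)
    stop("latitude must be within [-66, 66] degrees")
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  doy <- if (inherits(date, "Date"))
    as.POSIXlt(date)$yday + 1 else as.numeric(date)
  ra_mm <- 0.408 * extraterrestrial_radiation(doy, latitude)
  pet <- 0.0023 * ra_mm * ((tmin + tmax) / 2 + 17.8) * sqrt(tmax - tmin)
  pmax(0, pet)
}

#' Daily moisture index
#'
#' MI = precipitation - PET, a daily water-balance proxy (mm/day).
#'
#' @param prec precipitation mm/day.
#' @param pet potential evapotranspiration mm/day.
#' @return mm/day, elementwise.
#' @export
moisture_index <- function(prec, pet) {
  stopifnot(all(is.finite(prec)), all(is.finite(pet)))
  prec - pet
}

#' Find maximal dry spells
#'
#' A dry day receives less than `wet_threshold` mm of precipitation; a dry
#' spell is a maximal run of consecutive dry days. Lengths are inclusive.
#'
#' @param climate daily climate data.frame (`date`, `prec_mm`) with
#'   contiguous dates.
#' @param wet_threshold trace filter in mm (default 0.1).
#' @return data.frame `start`, `end`, `length_days`, sorted by start.
#' @export
dry_spells <- function(climate, wet_threshold = 0.1) {
  d <- climate$date
  if (any(diff(as.numeric(d)) != 1))
    stop("dry_spells requires contiguous daily dates")
  dry <- climate$prec_mm < wet_threshold
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(data.frame(start = as.Date(character()),
                                    end = as.Date(character()),
                                    length_days = integer()))
  data.frame(start = d[starts[keep]], end = d[ends[keep]],
             length_days = r$lengths[keep])
}

#' Aggregate daily climate to calendar months
#'
#' Temperatures are averaged; precipitation (and PET / moisture index when
#' present) are summed. Months without their full complement of days are
#' flagged as partial.
#'
#' @param climate daily climate data.frame.
#' @return data.frame `month` ("YYYY-MM"), `tmin_c`, `tmax_c`, `prec_mm`
#'   (and `pet_mm`, `mi_mm` if present), `n_days`, `complete`.
#' @export
monthly_climate <- function(climate) {
  ym <- .year_month(climate$date)
  agg <- function(x, f) tapply(x, ym, f)
  out <- data.frame(month = sort(unique(ym)))
  out$tmin_c <- as.numeric(agg(climate$tmin_c, mean)[out$month])
  out$tmax_c <- as.numeric(agg(climate$tmax_c, mean)[out$month])
  out$prec_mm <- as.numeric(agg(climate$prec_mm, sum)[out$month])
  for (v in c("pet_mm", "mi_mm"))
    if (v %in% names(climate))
      out[[v]] <- as.numeric(agg(climate[[v]], sum)[out$month])
  out$n_days <- as.integer(agg(climate$date, length)[out$month])
  first <- .month_date(out$month)
  # days in each month computed from its own calendar (handles leap years)
  ndays <- vapply(first, function(d) {
    as.integer(format(seq(d, by = "month", length.out = 2)[2] - 1, "%d"))
  }, integer(1))
  out$complete <- out$n_days == ndays
  out
}
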