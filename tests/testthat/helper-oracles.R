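# Independent oracles used across tests. Each is written directly from the
# defining formula / recurrence, separate from the package implementation.

# full-table dynamic-programming DTW (squared-Euclidean cost, sqrt at end)
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      D[i, j] <- (a[i - 1] - b[j - 1])^2 +
        min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
    }
  }
  sqrt(D[n + 1, m + 1])
}

# FAO-56 extraterrestrial radiation, coded step by step from the handbook
# equations (21)-(25): an independent implementation, not a call into the
# package.
ra_oracle <- function(doy, lat_deg) {
  Gsc <- 0.0820                                   # MJ m-2 min-1
  phi <- pi / 180 * lat_deg                       # Eq. 22
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)       # Eq. 23
  dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)   # Eq. 24
  ws <- acos(-tan(phi) * tan(dec))                # Eq. 25
  24 * 60 / pi * Gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))  # Eq. 21
}

# direct-formula Kling-Gupta components (population of the printed formula)
kge_oracle <- function(sim, obs) {
  r <- sum((sim - mean(sim)) * (obs - mean(obs))) /
    sqrt(sum((sim - mean(sim))^2) * sum((obs - mean(obs))^2))
  beta <- mean(sim) / mean(obs)
  gamma <- (sd(sim) / mean(sim)) / (sd(obs) / mean(obs))
  1 - sqrt((r - 1)^2 + (beta - 1)^2 + (gamma - 1)^2)
}

# build a regular 30-min single-tree series from a value vector
make_series <- function(values, tree_id = "T1",
                        start = "2019-01-01 00:00:00") {
  data.frame(
    timestamp = seq(as.POSIXct(start, tz = "UTC"), by = 1800,
                    length.out = length(values)),
    tree_id = tree_id,
    circumference_mm = values,
    stringsAsFactors = FALSE)
}

# a hand-made cumulative_curve object (season_dates only reads doy/cumulative)
make_curve <- function(doy, cumulative) {
  structure(list(doy = doy, cumulative = cumulative,
                 rate = c(diff(cumulative), 0), gam = NULL,
                 points = data.frame(doy = doy, y = cumulative),
                 monotone = !any(diff(cumulative) < 0)),
            class = "cumulative_curve")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
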