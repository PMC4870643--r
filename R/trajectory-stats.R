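#' Partition a track into 15-day periods since departure
#'
#' Consecutive half-open windows `[k*length, (k+1)*length)` days since the
#' departure fix. Each fix is assigned to exactly one period; empty periods
#' are kept (with zero fixes) so that downstream tables have a regular layout.
#'
#' @param track a track object.
#' @param length_days period length, days (default 15).
#' @param n_periods number of periods to report (default 6 = three months).
#' @return list of integer vectors indexing `track$fixes`, named by period
#'   index (1-based); attribute `departure_index` gives the departure fix.
#' @export
partition_periods <- function(track, length_days = 15, n_periods = 6) {
  i0 <- departure_index(track)
  if (is.na(i0)) stop("track has no departure fix", call. = FALSE)
  t0 <- as.numeric(track$fixes$time[i0])
  days <- (as.numeric(track$fixes$time) - t0) / 86400
  out <- lapply(seq_len(n_periods) - 1, function(k) {
    which(days >= k * length_days & days < (k + 1) * length_days)
  })
  names(out) <- as.character(seq_len(n_periods))
  attr(out, "departure_index") <- i0
  out
}

#' Path sinuosity (1 minus the straightness index)
#'
#' `S = 1 - beeline / path`, where beeline is the great-circle distance from
#' the first to the last fix and path is the summed great-circle step length.
#' 0 for a straight constant-heading path, 1 for a closed loop.
#'
#' @param lon,lat fix coordinates of a segment (>= 3 fixes), degrees.
#' @return S in `[0, 1]`; `NA_real_` if the path length is zero.
#' @export
sinuosity <- function(lon, lat) {
  n <- length(lon)
  if (n < 3) stop("sinuosity needs at least 3 fixes", call. = FALSE)
  steps <- haversine_km(lon[-n], lat[-n], lon[-1], lat[-1])
  path <- sum(steps)
  if (path <= 0) return(NA_real_)
  beeline <- haversine_km(lon[1], lat[1], lon[n], lat[n])
  max(0, min(1, 1 - beeline / path))
}

#' Daily distance travelled (DDT)
#'
#' Along-track great-circle distance per day, excluding transmitter-off gaps:
#' steps whose time gap exceeds `max_gap_hours` are dropped from both the
#' numerator (distance) and the denominator (elapsed time), so duty-cycled
#' sampling does not bias the estimate downwards.
#'
#' @param time POSIXct fix times (>= 2).
#' @param lon,lat fix coordinates, degrees.
#' @param max_gap_hours longest usable inter-fix gap, hours (default 36: the
#'   longest transmitter OFF period in a 10h-on/24h-off duty cycle plus slack).
#' @return km/day; `NA_real_` if no step is short enough.
#' @export
daily_distance <- function(time, lon, lat, max_gap_hours = 36) {
  n <- length(time)
  if (n < 2) stop("daily distance needs at least 2 fixes", call. = FALSE)
  gap_h <- diff(as.numeric(time)) / 3600
  keep <- gap_h <= max_gap_hours & gap_h > 0
  if (!any(keep)) return(NA_real_)
  d <- haversine_km(lon[-n][keep], lat[-n][keep], lon[-1][keep], lat[-1][keep])
  sum(d) / (sum(gap_h[keep]) / 24)
}

#' Departure bearing of a track
#'
#' Great-circle initial bearing from the colony to the first fix at least
#' `radius_km` away. The 100 km default radius excludes Argos noise and
#' pre-departure colony attendance.
#'
#' @param track a track object.
#' @param radius_km departure radius, km (default 100).
#' @return bearing in radians `[0, 2*pi)`; `NA_real_` if the track never
#'   reaches the radius.
#' @export
departure_bearing <- function(track, radius_km = 100) {
  d <- haversine_km(track$colony[["lon"]], track$colony[["lat"]],
                    track$fixes$lon, track$fixes$lat)
  i <- which(d >= radius_km)[1]
  if (is.na(i)) return(NA_real_)
  initial_bearing(track$colony[["lon"]], track$colony[["lat"]],
                  track$fixes$lon[i], track$fixes$lat[i])
}

#' Rhumb bearing of the position at 2 or 3 months
#'
#' Constant-azimuth (loxodrome) bearing from the colony to the fix nearest to
#' `30 * month` days since departure, within `tol_days`.
#'
#' @param track a track object.
#' @param month 2 or 3 (months are 30-day blocks since departure).
#' @param tol_days tolerance around the target day (default 3).
#' @return bearing in radians; `NA_real_` if no fix falls in the window.
#' @export
bearing_at_month <- function(track, month, tol_days = 3) {
  stopifnot(month %in% c(2, 3))
  s <- compute_nsd(track)
  target <- 30 * month
  dt <- abs(s$t - target)
  i <- which.min(dt)
  if (dt[i] > tol_days) return(NA_real_)
  rhumb_bearing(s$origin[["lon"]], s$origin[["lat"]], s$lon[i], s$lat[i])
}

#' Circular summary statistics and Rayleigh uniformity test
#'
#' Mean direction (atan2 of mean sine/cosine), mean resultant length R,
#' circular angular range (2*pi minus the largest gap between circularly
#' sorted angles), and the Rayleigh test of uniformity with `Z = n * R^2` and
#' the standard series approximation
#' `p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`,
#' clamped to `[0, 1]`.
#'
#' @param angles numeric vector of angles, radians (n >= 2).
#' @return object of class `circular_summary`: list with `mean_direction`,
#'   `R`, `angular_range`, `rayleigh_Z`, `rayleigh_p`, `n`.
#' @export
circular_summary <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles", call. = FALSE)
  C <- mean(cos(angles)); S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  mu <- wrap_2pi(atan2(S, C))
  a <- sort(wrap_2pi(angles))
  gaps <- diff(c(a, a[1] + 2 * pi))
  rng <- 2 * pi - max(gaps)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(list(mean_direction = mu, R = R, angular_range = rng,
                 rayleigh_Z = Z, rayleigh_p = p, n = n),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "<circular_summary> n = %d, mean = %.3f rad, R = %.3f, range = %.3f rad, Rayleigh p = %.4g\n",
    x$n, x$mean_direction, x$R, x$angular_range, x$rayleigh_p))
  invisible(x)
}

#' Mean latitude attained in a 30-day month since departure
#'
#' Arithmetic mean of fix latitudes in days `[30*(month-1), 30*month)` since
#' departure.
#'
#' @param track a track object.
#' @param month month index (1, 2 or 3).
#' @return degrees; `NA_real_` if the window holds no fix.
#' @export
mean_latitude <- function(track, month) {
  stopifnot(month %in% 1:3)
  s <- compute_nsd(track)
  sel <- s$t >= 30 * (month - 1) & s$t < 30 * month
  if (!any(sel)) return(NA_real_)
  mean(s$lat[sel])
}

#' Per-period trajectory statistics of one track
#'
#' Sinuosity, daily distance travelled, mean latitude and fix count for each
#' 15-day period since departure.
#'
#' @param track a track object.
#' @param length_days period length (default 15).
#' @param n_periods number of periods (default 6).
#' @return data frame with one row per period: `individual_id`, `species`,
#'   `period_index`, `sinuosity`, `ddt`, `mean_lat`, `n_fixes`.
#' @export
period_stats <- function(track, length_days = 15, n_periods = 6) {
  periods <- partition_periods(track, length_days, n_periods)
  rows <- lapply(seq_along(periods), function(k) {
    idx <- periods[[k]]
    fx <- track$fixes[idx, , drop = FALSE]
    s <- if (length(idx) >= 3) sinuosity(fx$lon, fx$lat) else NA_real_
    ddt <- if (length(idx) >= 2) daily_distance(fx$time, fx$lon, fx$lat) else NA_real_
    data.frame(individual_id = track$id, species = track$species,
               period_index = k, sinuosity = s, ddt = ddt,
               mean_lat = if (length(idx) > 0) mean(fx$lat) else NA_real_,
               n_fixes = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-period statistics for a set of tracks
#'
#' @param tracks list of track objects.
#' @inheritParams period_stats
#' @return stacked [period_stats()] data frame.
#' @export
period_stats_table <- function(tracks, length_days = 15, n_periods = 6) {
  out <- do.call(rbind, lapply(tracks, period_stats,
                               length_days = length_days, n_periods = n_periods))
  rownames(out) <- NULL
  out
}
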