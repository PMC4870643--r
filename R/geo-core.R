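#' @details
#' Spherical geometry primitives used throughout the package. All distances
#' are great-circle distances on a sphere of radius 6371.0088 km (IUGG mean
#' Earth radius). Bearings are in radians, clockwise from true north, in
#' `[0, 2*pi)`. Longitudes are normalised to `[-180, 180)` and all longitude
#' differences are taken on the shortest wrap, so circumpolar tracks are
#' handled correctly.
#' @keywords internal
"_PACKAGE"

#' Mean Earth radius (km) used for all spherical computations
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Normalise longitudes to [-180, 180)
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return normalised longitudes.
#' @export
normalize_lon <- function(lon) ((lon + 180) %% 360) - 180

# wrap an angle (radians) into [0, 2*pi)
wrap_2pi <- function(x) x %% (2 * pi)

# wrap an angular difference (radians) into [-pi, pi) (shortest turn)
wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

check_lat <- function(lat) {
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  invisible(lat)
}

#' Great-circle (haversine) distance in kilometres
#'
#' Distance between points on a sphere of radius [EARTH_RADIUS_KM], computed
#' with the haversine formula, which is numerically stable for short
#' baselines. Vectorised over all four arguments.
#'
#' @param lon1,lat1 origin coordinates, decimal degrees.
#' @param lon2,lat2 destination coordinates, decimal degrees.
#' @return distance in km (numeric vector).
#' @examples
#' # Crozet to Kerguelen
#' haversine_km(52.4, -46.2, 70.1, -49.4)
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  check_lat(lat1); check_lat(lat2)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dlat <- (lat2 - lat1) * pi / 180
  dlon <- (normalize_lon(lon2) - normalize_lon(lon1)) * pi / 180
  a <- sin(dlat / 2)^2 + cos(p1) * cos(p2) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Forward azimuth at the origin of the great circle towards the destination,
#' radians clockwise from true north in `[0, 2*pi)`.
#'
#' @inheritParams haversine_km
#' @return bearing in radians.
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  check_lat(lat1); check_lat(lat2)
  if (any(abs(normalize_lon(lon2) - normalize_lon(lon1)) < 1e-12 & abs(lat2 - lat1) < 1e-12)) {
    stop("bearing undefined for coincident points", call. = FALSE)
  }
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (normalize_lon(lon2) - normalize_lon(lon1)) * pi / 180
  # take the shortest wrap in longitude
  dl <- wrap_pi(dl)
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  wrap_2pi(atan2(y, x))
}

#' Rhumb-line (loxodrome) bearing
#'
#' Constant-azimuth bearing from origin to destination using the Mercator
#' projected latitude difference; the longitude difference is taken on the
#' shorter wrap. Radians clockwise from north in `[0, 2*pi)`.
#'
#' @inheritParams haversine_km
#' @return bearing in radians.
#' @export
rhumb_bearing <- function(lon1, lat1, lon2, lat2) {
  check_lat(lat1); check_lat(lat2)
  if (any(abs(normalize_lon(lon2) - normalize_lon(lon1)) < 1e-12 & abs(lat2 - lat1) < 1e-12)) {
    stop("bearing undefined for coincident points", call. = FALSE)
  }
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dpsi <- log(tan(pi / 4 + p2 / 2) / tan(pi / 4 + p1 / 2))
  dl <- wrap_pi((normalize_lon(lon2) - normalize_lon(lon1)) * pi / 180)
  wrap_2pi(atan2(dl, dpsi))
}

#' Destination point along a great circle
#'
#' Point reached travelling `dist_km` from (`lon`, `lat`) on initial bearing
#' `bearing` (radians clockwise from north).
#'
#' @param lon,lat start coordinates, decimal degrees.
#' @param bearing initial bearing, radians.
#' @param dist_km distance to travel, km.
#' @return list with elements `lon`, `lat` (degrees).
#' @export
destination_point <- function(lon, lat, bearing, dist_km) {
  check_lat(lat)
  p1 <- lat * pi / 180
  l1 <- lon * pi / 180
  d <- dist_km / EARTH_RADIUS_KM
  p2 <- asin(pmin(pmax(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(bearing), -1), 1))
  l2 <- l1 + atan2(sin(bearing) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  list(lon = normalize_lon(l2 * 180 / pi), lat = p2 * 180 / pi)
}

#' Index of the departure fix of a track
#'
#' The departure is the first fix at least `radius_km` from the colony; fixes
#' before it are colony attendance (or Argos noise around the colony) and are
#' excluded from days-at-sea accounting.
#'
#' @param track a track object (see [make_track()]).
#' @param radius_km departure radius, km (default 5).
#' @return integer index into the track's fixes, or `NA` if the bird never
#'   leaves the radius.
#' @export
departure_index <- function(track, radius_km = 5) {
  d <- haversine_km(track$colony[["lon"]], track$colony[["lat"]],
                    track$fixes$lon, track$fixes$lat)
  i <- which(d >= radius_km)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Net squared displacement series of a track
#'
#' The net squared displacement (NSD) is the squared great-circle (beeline)
#' distance between the natal colony and each location, in km^2. Time is
#' measured in fractional days since the departure fix (first fix at least
#' `departure_km` from the colony).
#'
#' With `unwrap = TRUE` the displacement is instead computed on unwrapped
#' coordinates: the trajectory's longitudes accumulate their winding (a bird
#' that circles the pole keeps gaining longitude) and the distance is the
#' plate-carree arc `R * sqrt(dlat^2 + (cos(mean lat) * dlon_unwrapped)^2)`.
#' This displacement keeps growing for circumpolar movements (where the
#' great-circle beeline folds back on itself) and agrees with the haversine
#' beeline to within a few percent at regional scales; it is what the NSD
#' model fits use (see [classify_movement()]).
#'
#' @param track a track object.
#' @param origin optional c(lon, lat) origin; defaults to the track's colony.
#' @param departure_km departure radius used to set t = 0 (km).
#' @param unwrap logical; use winding-aware unwrapped displacement (see
#'   Details).
#' @return an object of class `nsd_series`: list with `t` (days), `nsd`
#'   (km^2), `dist` (km), `origin`, `lon`, `lat`, `time`.
#' @export
compute_nsd <- function(track, origin = NULL, departure_km = 5, unwrap = FALSE) {
  if (is.null(origin)) origin <- track$colony
  if (nrow(track$fixes) == 0) stop("empty track", call. = FALSE)
  i0 <- departure_index(track, departure_km)
  if (is.na(i0)) i0 <- 1L
  fx <- track$fixes[seq(i0, nrow(track$fixes)), , drop = FALSE]
  if (unwrap) {
    # accumulate longitude winding along the trajectory
    dl <- (diff(fx$lon) + 180) %% 360 - 180
    lon_u <- fx$lon[1] + c(0, cumsum(dl))
    origin_lon_u <- fx$lon[1] + ((origin[["lon"]] - fx$lon[1] + 180) %% 360 - 180)
    dlat <- fx$lat - origin[["lat"]]
    dlon <- (lon_u - origin_lon_u) * cos((fx$lat + origin[["lat"]]) / 2 * pi / 180)
    d <- EARTH_RADIUS_KM * pi / 180 * sqrt(dlat^2 + dlon^2)
  } else {
    d <- haversine_km(origin[["lon"]], origin[["lat"]], fx$lon, fx$lat)
  }
  t_days <- as.numeric(difftime(fx$time, fx$time[1], units = "days"))
  structure(
    list(t = t_days, nsd = d^2, dist = d,
         origin = c(lon = unname(origin[["lon"]]), lat = unname(origin[["lat"]])),
         lon = fx$lon, lat = fx$lat, time = fx$time),
    class = "nsd_series"
  )
}

#' @export
print.nsd_series <- function(x, ...) {
  cat(sprintf("<nsd_series> %d fixes over %.1f days, max distance %.0f km\n",
              length(x$t), max(x$t), sqrt(max(x$nsd))))
  invisible(x)
}

#' Distance from the colony at a given time since departure
#'
#' Returns the colony distance of the fix nearest in time to `t_days` days
#' since departure (ties broken towards the earlier fix). If no fix falls
#' within `tol_days` of the requested time the track is considered too short
#' and `NA` is returned (with attribute `reason`).
#'
#' @param track a track object.
#' @param t_days requested time, days since departure.
#' @param origin optional c(lon, lat); defaults to the colony.
#' @param tol_days tolerance, days (default 3).
#' @return distance in km, or `NA_real_` with attribute
#'   `reason = "insufficient_duration"`.
#' @export
range_at <- function(track, t_days, origin = NULL, tol_days = 3) {
  s <- compute_nsd(track, origin)
  dt <- abs(s$t - t_days)
  i <- which.min(dt)  # which.min returns the first (earlier) of tied fixes
  if (dt[i] > tol_days) {
    return(structure(NA_real_, reason = "insufficient_duration"))
  }
  s$dist[i]
}
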