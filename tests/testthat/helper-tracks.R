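# shared builders for hand-constructed tracks

utc_hours <- function(n, start = "2014-01-15 00:00:00", interval_h = 6) {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * interval_h * 3600
}

# fixes along one great circle from the colony: exactly straight
straight_track <- function(n_fix = 41, step_km = 50, bearing = pi / 2,
                           interval_h = 6, colony = c(lon = 52.4, lat = -46.2),
                           id = "straight", species = "SIM") {
  p <- destination_point(colony[["lon"]], colony[["lat"]], bearing,
                         step_km * (seq_len(n_fix) - 1))
  make_track(id = id, species = species, age_class = "juvenile",
             colony = colony, time = utc_hours(n_fix, interval_h = interval_h),
             lon = p$lon, lat = p$lat, source = "simulated")
}

# fixes orbiting a centre point at (possibly varying) radius
orbit_track <- function(n_fix = 240, radius_km = 400, omega = 2 * pi / 80,
                        centre = c(lon = 52.4, lat = -46.2),
                        colony = centre, interval_h = 6,
                        radius_wobble_km = 0, id = "orbit", species = "SIM") {
  ang <- omega * (seq_len(n_fix) - 1)
  r <- radius_km + radius_wobble_km * sin(ang)
  p <- destination_point(centre[["lon"]], centre[["lat"]],
                         ang %% (2 * pi), r)
  make_track(id = id, species = species, age_class = "juvenile",
             colony = colony, time = utc_hours(n_fix, interval_h = interval_h),
             lon = p$lon, lat = p$lat, source = "simulated")
}

# an nsd_series holding an exact model curve
model_series <- function(model, params, t = seq(0, 90, by = 0.5)) {
  y <- eval_nsd_model(model, params, t)
  structure(list(t = t, nsd = y, dist = sqrt(y),
                 origin = c(lon = 0, lat = 0)),
            class = "nsd_series")
}

# a stub nsd_fit for selection tests
stub_fit <- function(model, cc, plausible = TRUE) {
  structure(list(model = model, params = NULL, cc = cc, converged = TRUE,
                 plausible = plausible, residual_sd = NA_real_,
                 fitted = NULL, sse = NA_real_),
            class = "nsd_fit")
}
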