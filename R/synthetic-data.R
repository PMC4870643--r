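#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; falls back to the circular uniform for
#' near-zero concentration.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- stats::runif(1)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) break
    }
    out[i] <- wrap_2pi(mu + sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1)))
  }
  out
}

#' Simulation configuration for one synthetic track
#'
#' Defaults describe a juvenile procellariiform fledging from Crozet: a
#' 90-day trip, Argos transmitter on a 12 h ON / 60 h OFF duty cycle with a
#' roughly 6-hourly fix cadence while ON (about 0.67 locations per day), and
#' mode-specific movement parameters (see the package vignette for their
#' rationale):
#' \itemize{
#'   \item `home_range`: wandering within ~350 km of the colony at 200 km/day;
#'   \item `nomad`: eastward biased correlated random walk at 350 km/day,
#'     cruising along 55 degrees S (the Westerlies corridor);
#'   \item `half_migration`: directed transit of `transit_days` days to a
#'     settlement point `settlement_km` away, then residence there;
#'   \item `migration`: half-migration plus a mirrored return leg ending back
#'     at the colony;
#'   \item `looping`: steady travel around a circle through the colony of
#'     radius `loop_radius_km`, so the bird repeatedly returns towards the
#'     colony while ranging up to twice the radius away.
#' }
#'
#' @param mode movement phenotype.
#' @param colony c(lon, lat), degrees; default Crozet (52.4 E, 46.2 S).
#' @param duration_days trip duration.
#' @param nominal_speed_kmday along-track speed, km/day (mode default if NULL).
#' @param heading_mean mean departure/settlement heading, radians.
#' @param heading_kappa von Mises concentration of the drawn heading.
#' @param transit_days transit duration for migration-family modes.
#' @param settlement_km colony-to-settlement distance for migration-family
#'   modes.
#' @param loop_radius_km loop radius for the looping mode.
#' @param cruise_lat latitude band for the nomad mode, degrees.
#' @param home_radius_km wander radius for the home-range mode.
#' @param home_tau_days relaxation time of the home-range expansion: the
#'   patrolled distance approaches `home_radius_km` as
#'   `sqrt(1 - exp(-t/home_tau_days))`, so the squared displacement relaxes
#'   exponentially towards its asymptote.
#' @param home_jitter_km stationary sd of the radial jitter around the
#'   patrolled distance for the home-range mode.
#' @param duty_cycle c(hours_on, hours_off).
#' @param fix_interval_hours latent-path subsampling interval before the duty
#'   cycle is applied.
#' @param noise_kind "argos" or "gls".
#' @param noise_sd_km per-axis Gaussian positional error sd; defaults: 15 km
#'   (argos), 152.9 km (gls; median radial error 180 km).
#' @param seed integer; fixes all randomness of the track.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(mode,
                       colony = c(lon = 52.4, lat = -46.2),
                       duration_days = 90,
                       nominal_speed_kmday = NULL,
                       heading_mean = pi / 4,
                       heading_kappa = 20,
                       transit_days = 15,
                       settlement_km = 4000,
                       loop_radius_km = 1000,
                       cruise_lat = -55,
                       home_radius_km = 350,
                       home_tau_days = 12,
                       home_jitter_km = 25,
                       duty_cycle = c(12, 60),
                       fix_interval_hours = 6,
                       noise_kind = c("argos", "gls"),
                       noise_sd_km = NULL,
                       seed = 1L) {
  mode <- match.arg(mode, c("home_range", "nomad", "half_migration",
                            "migration", "looping"))
  noise_kind <- match.arg(noise_kind)
  if (is.null(nominal_speed_kmday)) {
    nominal_speed_kmday <- switch(mode, home_range = 200, nomad = 350,
                                  half_migration = NA, migration = NA,
                                  looping = 240)
  }
  if (is.null(noise_sd_km)) {
    noise_sd_km <- if (noise_kind == "argos") 15 else 180 / sqrt(2 * log(2))
  }
  if (mode %in% c("half_migration", "migration") && settlement_km <= 0) {
    stop("settlement_km must be positive for migration-family modes",
         call. = FALSE)
  }
  stopifnot(duration_days > 0, heading_kappa >= 0, transit_days > 0,
            loop_radius_km > 0, all(duty_cycle >= 0), fix_interval_hours >= 1)
  structure(list(mode = mode, colony = colony, duration_days = duration_days,
                 nominal_speed_kmday = nominal_speed_kmday,
                 heading_mean = heading_mean, heading_kappa = heading_kappa,
                 transit_days = transit_days, settlement_km = settlement_km,
                 loop_radius_km = loop_radius_km, cruise_lat = cruise_lat,
                 home_radius_km = home_radius_km,
                 home_tau_days = home_tau_days,
                 home_jitter_km = home_jitter_km, duty_cycle = duty_cycle,
                 fix_interval_hours = fix_interval_hours,
                 noise_kind = noise_kind, noise_sd_km = noise_sd_km,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# correlated wander with attraction to a ring of geodesic radius radius_km
# around a centre: birds commute at their residence range rather than sitting
# on the centre. state: list(lon, lat, heading); returns updated state.
wander_step <- function(state, center, radius_km, step_km, kappa = 2,
                        bias_cap = 1) {
  d <- haversine_km(center[["lon"]], center[["lat"]], state$lon, state$lat)
  if (d > 1) {
    bto <- initial_bearing(state$lon, state$lat, center[["lon"]], center[["lat"]])
  } else {
    bto <- stats::runif(1, 0, 2 * pi)
  }
  # outside the ring head inwards with a strong restoring weight (saturating
  # over a quarter of the radius); inside, only a gentle outward tilt capped
  # at bias_cap, so the range fills diffusively rather than ballistically
  if (d >= radius_km) {
    bias <- bto
    w <- min(1, (d - radius_km) / (0.25 * radius_km))
  } else {
    bias <- wrap_2pi(bto + pi)
    w <- min(bias_cap, (radius_km - d) / radius_km)
  }
  tx <- (1 - w) * cos(state$heading) + w * cos(bias)
  ty <- (1 - w) * sin(state$heading) + w * sin(bias)
  target <- if (abs(tx) + abs(ty) < 1e-12) bias else atan2(ty, tx)
  h <- rvonmises(1, target, kappa)
  p <- destination_point(state$lon, state$lat, h, step_km)
  list(lon = p$lon, lat = p$lat, heading = h)
}

# directed transit towards a target point: one hourly step
transit_step <- function(state, target, step_km, kappa = 15) {
  bto <- initial_bearing(state$lon, state$lat, target[["lon"]], target[["lat"]])
  h <- rvonmises(1, bto, kappa)
  p <- destination_point(state$lon, state$lat, h, step_km)
  list(lon = p$lon, lat = p$lat, heading = h)
}

# build the hourly latent path for a config; returns data.frame(lon, lat)
simulate_latent_path <- function(config) {
  n <- config$duration_days * 24
  lon <- numeric(n + 1); lat <- numeric(n + 1)
  colony <- config$colony
  lon[1] <- colony[["lon"]]; lat[1] <- colony[["lat"]]
  mode <- config$mode

  if (mode == "home_range") {
    # progressive range expansion: the fledgling patrols at a colony distance
    # that relaxes exponentially towards the home-range radius (so the NSD is
    # asymptotic by construction), exploring tangentially along that contour
    # with direction reversals (no net rotation about the colony) and a small
    # radial jitter (hourly AR(1), ~1-day relaxation)
    step <- config$nominal_speed_kmday / 24
    tau_h <- config$home_tau_days * 24
    r <- config$home_radius_km
    psi0 <- stats::runif(1, 0, 2 * pi)
    off <- 0  # angular offset from the sector centre psi0
    sgn <- if (stats::runif(1) < 0.5) -1 else 1
    u <- 0
    a <- 1 - 1 / 24
    sig <- config$home_jitter_km * sqrt(1 - a^2)
    for (i in seq_len(n)) {
      d_target <- r * sqrt(1 - exp(-i / tau_h))
      u <- a * u + stats::rnorm(1, 0, sig)
      if (stats::runif(1) < 1 / 36) sgn <- -sgn
      # patrol a bounded sector: never orbit the colony
      if (abs(off) > pi / 2) sgn <- -sign(off)
      off <- off + sgn * step / max(d_target, 20)
      psi <- wrap_2pi(psi0 + off)
      p <- destination_point(colony[["lon"]], colony[["lat"]], psi,
                             max(1, d_target + u))
      lon[i + 1] <- p$lon; lat[i + 1] <- p$lat
    }
  } else if (mode == "nomad") {
    step <- config$nominal_speed_kmday / 24
    kappa <- min(config$heading_kappa, 8)
    st <- list(lon = lon[1], lat = lat[1], heading = pi / 2)
    for (i in seq_len(n)) {
      target <- pi / 2 + atan(0.15 * (st$lat - config$cruise_lat))
      h <- rvonmises(1, target, kappa)
      p <- destination_point(st$lon, st$lat, h, step)
      st <- list(lon = p$lon, lat = p$lat, heading = h)
      lon[i + 1] <- st$lon; lat[i + 1] <- st$lat
    }
  } else if (mode %in% c("half_migration", "migration")) {
    h0 <- rvonmises(1, config$heading_mean, config$heading_kappa)
    target <- destination_point(colony[["lon"]], colony[["lat"]], h0,
                                config$settlement_km)
    target <- c(lon = target$lon, lat = target$lat)
    step <- config$settlement_km / config$transit_days / 24
    settle_radius <- 200
    settle_step <- 150 / 24
    return_start <- if (mode == "migration") {
      (config$duration_days - config$transit_days - 10) * 24
    } else {
      Inf
    }
    phase <- "out"
    st <- list(lon = lon[1], lat = lat[1], heading = h0)
    for (i in seq_len(n)) {
      if (phase == "out") {
        d <- haversine_km(st$lon, st$lat, target[["lon"]], target[["lat"]])
        if (d < 1.5 * step) phase <- "settle"
      }
      if (phase == "settle" && i >= return_start) phase <- "return"
      if (phase == "return") {
        d <- haversine_km(st$lon, st$lat, colony[["lon"]], colony[["lat"]])
        if (d < 1.5 * step) phase <- "home"
      }
      st <- switch(phase,
        out = transit_step(st, target, step),
        settle = wander_step(st, target, settle_radius, settle_step),
        "return" = transit_step(st, colony, step),
        home = wander_step(st, colony, 100, 100 / 24))
      lon[i + 1] <- st$lon; lat[i + 1] <- st$lat
    }
  } else if (mode == "looping") {
    # circuit centre 0.6 radii from the colony: the colony sits inside the
    # circuit, so the bird ranges 0.4-1.6 radii away and repeatedly swings
    # back towards it
    center <- destination_point(colony[["lon"]], colony[["lat"]],
                                config$heading_mean, 0.6 * config$loop_radius_km)
    center <- c(lon = center$lon, lat = center$lat)
    r <- config$loop_radius_km
    step <- config$nominal_speed_kmday / 24
    # leave the colony to the nearest point of the circuit, then orbit
    entry <- destination_point(colony[["lon"]], colony[["lat"]],
                               wrap_2pi(config$heading_mean + pi), 0.4 * r)
    psi0 <- initial_bearing(center[["lon"]], center[["lat"]],
                            entry$lon, entry$lat)
    n_transit <- ceiling(0.4 * r / step)
    st <- list(lon = lon[1], lat = lat[1], heading = config$heading_mean + pi)
    # angular speed along the small circle of geodesic radius r
    omega <- step / (EARTH_RADIUS_KM * sin(r / EARTH_RADIUS_KM))
    jitter <- 0
    rho <- exp(-1 / 24)  # radial jitter relaxes on a 1-day scale
    sd_j <- 30 * sqrt(1 - rho^2)
    for (i in seq_len(n)) {
      if (i <= n_transit) {
        st <- transit_step(st, c(lon = entry$lon, lat = entry$lat), step)
        lon[i + 1] <- st$lon; lat[i + 1] <- st$lat
      } else {
        jitter <- jitter * rho + stats::rnorm(1, 0, sd_j)
        p <- destination_point(center[["lon"]], center[["lat"]],
                               wrap_2pi(psi0 + omega * (i - n_transit)), r + jitter)
        lon[i + 1] <- p$lon; lat[i + 1] <- p$lat
      }
    }
  }
  data.frame(lon = lon, lat = lat)
}

#' Simulate one synthetic track
#'
#' Builds an hourly latent path for the configured movement mode, subsamples
#' it to the fix cadence, applies the transmitter duty cycle and adds
#' positional noise. Deterministic given `config$seed`; the caller's RNG
#' state is untouched. The generating truth (mode and parameters) is attached
#' as attribute `truth`, and the hourly latent path as attribute `latent`.
#'
#' @param config a [sim_config()].
#' @param id individual identifier (default derived from mode and seed).
#' @param species species code stored on the track.
#' @param start POSIXct start time of the track.
#' @return a `seabird_track`.
#' @export
simulate_track <- function(config, id = NULL,
                           species = "SIM",
                           start = as.POSIXct("2014-01-15 00:00:00", tz = "UTC")) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(id)) id <- sprintf("%s_%04d", config$mode, config$seed)
  with_seed(config$seed, {
    path <- simulate_latent_path(config)
    n <- nrow(path)
    time <- start + (seq_len(n) - 1) * 3600
    latent <- data.frame(time = time, lon = path$lon, lat = path$lat)
    keep <- ((seq_len(n) - 1) %% config$fix_interval_hours) == 0
    track <- make_track(id = id, species = species, age_class = "juvenile",
                        colony = config$colony, time = time[keep],
                        lon = path$lon[keep], lat = path$lat[keep],
                        source = "simulated")
    track <- apply_duty_cycle(track, config$duty_cycle)
    track <- add_positional_noise(track, config$noise_sd_km, config$noise_kind)
    attr(track, "truth") <- list(mode = config$mode,
                                 settlement_km = config$settlement_km,
                                 nominal_speed_kmday = config$nominal_speed_kmday,
                                 loop_radius_km = config$loop_radius_km,
                                 seed = config$seed)
    attr(track, "latent") <- latent
    track
  })
}

#' Apply a transmitter duty cycle to a track
#'
#' Retains only fixes whose time-of-cycle falls inside the ON window; the
#' cycle is anchored at the track's first fix. `c(h_on, 0)` leaves the track
#' unchanged.
#'
#' @param track a track object.
#' @param pattern c(hours_on, hours_off).
#' @return the thinned track.
#' @export
apply_duty_cycle <- function(track, pattern) {
  h_on <- pattern[[1]]; h_off <- pattern[[2]]
  stopifnot(h_on > 0, h_off >= 0)
  if (h_off == 0) return(track)
  t_h <- (as.numeric(track$fixes$time) - as.numeric(track$fixes$time[1])) / 3600
  keep <- (t_h %% (h_on + h_off)) < h_on
  out <- track
  out$fixes <- track$fixes[keep, , drop = FALSE]
  rownames(out$fixes) <- NULL
  out
}

#' Add isotropic positional noise to a track
#'
#' Displaces each fix by an isotropic Gaussian error (independent per-axis sd
#' `sd_km`). The GLS default is calibrated so the median radial error is
#' 180 km (`sd = 180 / sqrt(2 * log(2))` per axis, the Rayleigh-median
#' relation). Timestamps are untouched.
#'
#' @param track a track object.
#' @param sd_km per-axis error sd, km; if `NULL`, the `kind` default is used
#'   (argos: 15 km; gls: 152.9 km).
#' @param kind "argos" or "gls".
#' @param seed optional seed; if supplied the caller's RNG state is untouched.
#' @return the noised track.
#' @export
add_positional_noise <- function(track, sd_km = NULL, kind = c("argos", "gls"),
                                 seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(sd_km)) sd_km <- if (kind == "argos") 15 else 180 / sqrt(2 * log(2))
  stopifnot(sd_km >= 0)
  if (sd_km == 0) return(track)
  run <- function() {
    n <- nrow(track$fixes)
    dx <- stats::rnorm(n, 0, sd_km)
    dy <- stats::rnorm(n, 0, sd_km)
    p <- destination_point(track$fixes$lon, track$fixes$lat,
                           atan2(dx, dy), sqrt(dx^2 + dy^2))
    out <- track
    out$fixes$lon <- p$lon
    out$fixes$lat <- p$lat
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Default simulation configuration per movement mode
#'
#' The study conditions used by the package's validation suite: Crozet
#' colony, 90-day juvenile trips, 12h/60h duty cycle over a 6-hourly cadence,
#' Argos-grade noise; nomads at 350 km/day along 55 S, half-migrants and
#' migrants settling 4000 km away after a 15-day transit, loopers on a
#' 1000 km-radius circuit at 240 km/day, home-ranging birds within 350 km at
#' 200 km/day.
#'
#' @param mode movement phenotype.
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
default_sim_config <- function(mode, seed = 1L) {
  sim_config(mode = mode, seed = seed)
}

#' Simulate a cohort of tracks across movement modes
#'
#' Per-track seeds are derived deterministically as `seed + index - 1` in
#' mode-major order (the default cohort therefore uses seeds 1 to 50), so
#' reruns are byte-identical. A truth table accompanies the tracks for
#' recovery scoring.
#'
#' @param n_per_mode tracks per mode.
#' @param seed master seed.
#' @param modes movement phenotypes to include.
#' @return list with `tracks` (named list) and `truth` (data frame: id, mode,
#'   settlement_km, nominal_speed_kmday, seed).
#' @export
simulate_cohort <- function(n_per_mode = 10, seed = 1L,
                            modes = c("home_range", "nomad", "half_migration",
                                      "migration", "looping")) {
  stopifnot(n_per_mode >= 1)
  tracks <- list()
  rows <- list()
  idx <- 0L
  for (mode in modes) {
    for (k in seq_len(n_per_mode)) {
      idx <- idx + 1L
      trk_seed <- as.integer(seed) + idx - 1L
      cfg <- default_sim_config(mode, seed = trk_seed)
      id <- sprintf("%s_%03d", mode, k)
      tr <- simulate_track(cfg, id = id)
      tracks[[id]] <- tr
      truth <- attr(tr, "truth")
      rows[[idx]] <- data.frame(id = id, mode = mode,
                                settlement_km = truth$settlement_km,
                                nominal_speed_kmday = truth$nominal_speed_kmday,
                                seed = trk_seed, stringsAsFactors = FALSE)
    }
  }
  list(tracks = tracks, truth = do.call(rbind, rows))
}

#' Generate synthetic environmental rasters
#'
#' A smooth abyssal basin at -4500 m with one shelf ridge rising to -200 m
#' along a configurable arc (the set of points at `shelf_radius_km` from
#' `shelf_center`); a latitudinal SST gradient (25 C at 20 S to -1 C at 65 S)
#' with seeded noise; and background chlorophyll-a of 0.1 mg m-3 with patches
#' up to ~3 mg m-3 over the shelf.
#'
#' @param extent c(lon_min, lon_max, lat_min, lat_max), degrees.
#' @param cell_deg cell size, degrees.
#' @param seed seed for the noise fields.
#' @param shelf_center c(lon, lat) of the shelf arc centre.
#' @param shelf_radius_km arc radius (0 gives a circular bank).
#' @param shelf_width_km Gaussian e-folding width of the ridge.
#' @return named list of `env_raster`s: `bathymetry_m`, `sst_c`, `chla_mg_m3`.
#' @export
make_env_rasters <- function(extent = c(20, 140, -70, -20), cell_deg = 0.5,
                             seed = 1L,
                             shelf_center = c(lon = 114, lat = -31),
                             shelf_radius_km = 600,
                             shelf_width_km = 300) {
  stopifnot(cell_deg > 0)
  lon <- seq(extent[1] + cell_deg / 2, extent[2] - cell_deg / 2, by = cell_deg)
  lat <- seq(extent[3] + cell_deg / 2, extent[4] - cell_deg / 2, by = cell_deg)
  with_seed(seed, {
    dist_c <- outer(lat, lon, function(la, lo) {
      haversine_km(shelf_center[["lon"]], shelf_center[["lat"]], lo, la)
    })
    dist_arc <- abs(dist_c - shelf_radius_km)
    ridge <- exp(-(dist_arc / shelf_width_km)^2)
    bathy <- -4500 + 4300 * ridge
    sst <- matrix(rep(25 + (lat + 20) * 26 / 45, length(lon)),
                  nrow = length(lat)) +
      matrix(stats::rnorm(length(lat) * length(lon), 0, 0.5),
             nrow = length(lat))
    chla <- 0.1 + 2.9 * ridge *
      matrix(stats::rlnorm(length(lat) * length(lon), 0, 0.3),
             nrow = length(lat))
    list(bathymetry_m = env_raster("bathymetry_m", lon, lat, bathy),
         sst_c = env_raster("sst_c", lon, lat, sst),
         chla_mg_m3 = env_raster("chla_mg_m3", lon, lat, chla))
  })
}
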