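test_that("longitudes normalise into [-180, 180) and the map is idempotent", {
  expect_equal(normalize_lon(c(0, 180, -180, 359, -541, 52.4)),
               c(0, -180, -180, -1, 179, 52.4))
  x <- runif(200, -1000, 1000)
  expect_identical(normalize_lon(normalize_lon(x)), normalize_lon(x))
  expect_true(all(normalize_lon(x) >= -180 & normalize_lon(x) < 180))
})

test_that("haversine distance is symmetric, non-negative and zero on the diagonal", {
  set.seed(1)
  lon <- runif(100, -180, 180); lat <- runif(100, -85, 85)
  lon2 <- runif(100, -180, 180); lat2 <- runif(100, -85, 85)
  d <- haversine_km(lon, lat, lon2, lat2)
  expect_true(all(d >= 0))
  expect_true(all(d <= pi * EARTH_RADIUS_KM + 1e-9))
  expect_equal(d, haversine_km(lon2, lat2, lon, lat))
  expect_equal(haversine_km(lon, lat, lon, lat), rep(0, 100))
})

test_that("antimeridian crossings take the short way round", {
  expect_lt(haversine_km(179.5, -50, -179.5, -50), 100)
  b <- initial_bearing(179.5, -50, -179.5, -50)
  expect_lt(abs(b - pi / 2), 0.05)  # eastwards, not the long way west
})

test_that("latitude outside [-90, 90] is rejected", {
  expect_error(haversine_km(0, 91, 10, 10), "latitude")
  expect_error(destination_point(0, -90.5, 0, 10), "latitude")
})

test_that("bearings live in [0, 2*pi) and coincident points are rejected", {
  set.seed(2)
  for (i in 1:50) {
    b <- initial_bearing(runif(1, -180, 180), runif(1, -80, 80),
                         runif(1, -180, 180), runif(1, -80, 80))
    expect_true(b >= 0 && b < 2 * pi)
  }
  expect_error(initial_bearing(10, 10, 10, 10), "coincident")
  expect_error(rhumb_bearing(10, 10, 10, 10), "coincident")
})

test_that("a rhumb line due east keeps a constant 90-degree bearing", {
  expect_equal(rhumb_bearing(0, -46, 40, -46), pi / 2, tolerance = 1e-12)
  expect_equal(rhumb_bearing(40, -46, 0, -46), 3 * pi / 2, tolerance = 1e-12)
  expect_equal(rhumb_bearing(0, -60, 0, -20), 0, tolerance = 1e-12)
})

test_that("destination_point round-trips distance and bearing", {
  set.seed(3)
  for (i in 1:50) {
    lon <- runif(1, -180, 180); lat <- runif(1, -70, 70)
    b <- runif(1, 0, 2 * pi); d <- runif(1, 1, 5000)
    p <- destination_point(lon, lat, b, d)
    expect_equal(haversine_km(lon, lat, p$lon, p$lat), d, tolerance = 1e-6)
    expect_lt(abs(((initial_bearing(lon, lat, p$lon, p$lat) - b + pi) %%
                     (2 * pi)) - pi), 1e-6)
  }
})

test_that("departure index finds the first fix beyond the colony radius", {
  tr <- straight_track(n_fix = 10, step_km = 2)  # fixes at 0, 2, 4, ... km
  expect_identical(departure_index(tr, radius_km = 5), 4L)  # first >= 5 km is 6 km
  expect_identical(departure_index(tr, radius_km = 1000), NA_integer_)
})

test_that("NSD is the squared colony distance with time zeroed at departure", {
  tr <- straight_track(n_fix = 20, step_km = 50)
  s <- compute_nsd(tr)
  expect_s3_class(s, "nsd_series")
  expect_equal(s$t[1], 0)
  expect_equal(s$nsd, s$dist^2)
  d_direct <- haversine_km(tr$colony[["lon"]], tr$colony[["lat"]], s$lon, s$lat)
  expect_equal(s$dist, d_direct, tolerance = 1e-12)
  # the 50 km first fix is the departure (>= 5 km), so n is preserved minus none
  expect_length(s$t, 19)  # fix 1 sits on the colony and is pre-departure
})

test_that("unwrapped displacement keeps growing on a circumpolar track while the great-circle beeline folds back", {
  colony <- c(lon = 0, lat = -55)
  lons <- seq(0, 350, by = 10)  # full westless eastward sweep at fixed latitude
  tr <- make_track("circum", "SIM", "juvenile", colony,
                   time = utc_hours(length(lons)), lon = lons,
                   lat = rep(-55, length(lons)), source = "simulated")
  wrapped <- compute_nsd(tr)
  unwrapped <- compute_nsd(tr, unwrap = TRUE)
  expect_lt(max(wrapped$dist), pi * EARTH_RADIUS_KM)
  expect_true(all(diff(unwrapped$dist) > 0))
  expect_gt(max(unwrapped$dist), max(wrapped$dist))
  # at a quarter turn the two displacements agree to within a few percent
  i <- which.min(abs(lons - 40))
  expect_equal(unwrapped$dist[i - 1], wrapped$dist[i - 1], tolerance = 0.05)
})

test_that("range_at returns the nearest fix distance or a reasoned NA", {
  tr <- straight_track(n_fix = 41, step_km = 50)  # 10 days at 200 km/day
  r <- range_at(tr, 5)
  expect_equal(r, 50 + 5 * 200, tolerance = 1e-6)
  short <- range_at(tr, 90)
  expect_true(is.na(short))
  expect_identical(attr(short, "reason"), "insufficient_duration")
})
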