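test_that("track construction validates ordering and normalises coordinates", {
  tm <- utc_hours(3)
  tr <- make_track("a", "WAAL", "juvenile", c(lon = 412.4, lat = -46.2),
                   time = tm, lon = c(200, 10, 20), lat = c(-40, -41, -42))
  expect_s3_class(tr, "seabird_track")
  expect_equal(tr$colony[["lon"]], 52.4)
  expect_equal(tr$fixes$lon[1], -160)
  expect_error(make_track("a", "WAAL", "juvenile", c(lon = 0, lat = 0),
                          time = tm[c(1, 3, 2)], lon = 1:3, lat = 1:3),
               "increasing")
  expect_error(make_track("a", "WAAL", "fledgling", c(lon = 0, lat = 0),
                          time = tm, lon = 1:3, lat = 1:3))
})

test_that("reading counts unparseable and duplicate rows and keeps the ledger balanced", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,species,age_class,datetime,lon,lat",
    "b1,WAAL,juvenile,2014-01-15T00:00:00,52.4,-46.2",
    "b1,WAAL,juvenile,2014-01-15T06:00:00,53.0,-46.5",
    "b1,WAAL,juvenile,2014-01-15T06:00:00,53.1,-46.6",  # duplicate timestamp
    "b1,WAAL,juvenile,not-a-time,53.5,-47.0",           # unparseable
    "b1,WAAL,juvenile,2014-01-15T12:00:00,bad,-47.0",   # unparseable
    "b2,DIPE,juvenile,2014-01-15T00:00:00,51.0,-46.0",
    "b2,DIPE,juvenile,2014-01-15T06:00:00,51.5,-46.3"), f)
  colonies <- data.frame(id = c("b1", "b2"), lon = c(52.4, 51.0),
                         lat = c(-46.2, -46.0))
  rd <- suppressMessages(read_tracks(f, colonies = colonies))
  rep <- rd$report
  expect_identical(rep$n_input, 7L)
  expect_identical(rep$n_removed_unparseable, 2L)
  expect_identical(rep$n_removed_duplicate, 1L)
  expect_identical(rep$n_output,
                   rep$n_input - rep$n_removed_unparseable -
                     rep$n_removed_duplicate - rep$n_removed_speed)
  expect_identical(rep$n_output, 4L)
  expect_named(rd$tracks, c("b1", "b2"))
  expect_identical(nrow(rd$tracks$b1$fixes), 2L)
})

test_that("tab-delimited input is autodetected and a missing column is a hard error", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tspecies\tage_class\tdatetime\tlon\tlat",
               "c1\tWAAL\tadult\t2014-02-01 00:00\t60\t-50",
               "c1\tWAAL\tadult\t2014-02-01 06:00\t61\t-50"), f)
  rd <- suppressMessages(
    read_tracks(f, colonies = data.frame(id = "c1", lon = 60, lat = -50)))
  expect_identical(rd$report$n_output, 2L)
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("id,species,datetime,lon,lat",
               "c1,WAAL,2014-02-01T00:00:00,60,-50"), f2)
  expect_error(suppressMessages(read_tracks(f2)), "age_class")
})

test_that("write_tracks and read_tracks round-trip coordinates and times", {
  tr <- straight_track(n_fix = 8, step_km = 123.4)
  f <- tempfile(fileext = ".csv")
  write_tracks(tr, f)
  rd <- suppressMessages(read_tracks(
    f, colonies = data.frame(id = tr$id, lon = tr$colony[["lon"]],
                             lat = tr$colony[["lat"]]),
    source = "simulated"))
  back <- rd$tracks[[tr$id]]
  expect_equal(back$fixes$lon, tr$fixes$lon, tolerance = 1e-9)
  expect_equal(back$fixes$lat, tr$fixes$lat, tolerance = 1e-9)
  expect_identical(as.numeric(back$fixes$time), as.numeric(tr$fixes$time))
  expect_identical(back$species, tr$species)
})

test_that("the speed filter removes the implausible fix and leaves all speeds under the ceiling", {
  tr <- straight_track(n_fix = 20, step_km = 50)  # ~8.3 km/h throughout
  fx <- tr$fixes
  # teleport fix 10 by 2000 km: both adjacent segments exceed any sane speed
  p <- destination_point(fx$lon[10], fx$lat[10], 0, 2000)
  fx$lon[10] <- p$lon; fx$lat[10] <- p$lat
  bad <- tr; bad$fixes <- fx
  out <- speed_filter(bad, vmax = 90)
  expect_identical(out$report$n_removed_speed, 1L)
  expect_identical(nrow(out$track$fixes), 19L)
  expect_identical(out$report$n_output, 19L)
  v <- with(out$track$fixes,
            haversine_km(head(lon, -1), head(lat, -1), lon[-1], lat[-1]) /
              (diff(as.numeric(time)) / 3600))
  expect_true(all(v <= 90))
  # a clean track passes untouched
  clean <- speed_filter(tr, vmax = 90)
  expect_identical(clean$report$n_removed_speed, 0L)
  expect_identical(clean$track$fixes, tr$fixes)
})

test_that("block smoothing averages windows and survives the antimeridian", {
  tm <- utc_hours(6, interval_h = 12)  # all within one 3-day window
  tr <- make_track("am", "SIM", "juvenile", c(lon = 179, lat = -50),
                   time = tm, lon = c(179.4, 179.8, -179.8, -179.4, 179.6, -179.9),
                   lat = rep(-50, 6), source = "gls")
  sm <- smooth_track(tr, window_days = 3)
  expect_identical(nrow(sm$fixes), 1L)
  # the average must sit near the antimeridian, not near Greenwich
  expect_gt(abs(sm$fixes$lon), 179)
  expect_equal(sm$fixes$lat, -50)
})

test_that("sampling rate is fixes per day and degenerates to NA", {
  tr <- straight_track(n_fix = 13, interval_h = 6)  # 3 days, 13 fixes
  expect_equal(sampling_rate(tr), 13 / 3)
  one <- straight_track(n_fix = 1)
  expect_true(is.na(sampling_rate(one)))
})
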