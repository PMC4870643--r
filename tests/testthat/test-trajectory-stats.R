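test_that("period partitioning is disjoint, exhaustive over the horizon and anchored at departure", {
  tr <- straight_track(n_fix = 200, step_km = 25, interval_h = 12)  # 100 days
  periods <- partition_periods(tr, length_days = 15, n_periods = 6)
  expect_length(periods, 6)
  idx <- unlist(periods)
  expect_identical(anyDuplicated(idx), 0L)
  i0 <- attr(periods, "departure_index")
  t0 <- as.numeric(tr$fixes$time[i0])
  days <- (as.numeric(tr$fixes$time) - t0) / 86400
  expect_setequal(idx, which(days >= 0 & days < 90))
  expect_true(all(days[periods[["3"]]] >= 30 & days[periods[["3"]]] < 45))
})

test_that("sinuosity is zero on a great circle, one on a closed loop, and bounded", {
  tr <- straight_track(n_fix = 30, step_km = 80)
  expect_equal(sinuosity(tr$fixes$lon, tr$fixes$lat), 0, tolerance = 1e-9)
  loop <- orbit_track(n_fix = 41, omega = 2 * pi / 40)  # ends where it starts
  expect_equal(sinuosity(loop$fixes$lon, loop$fixes$lat), 1, tolerance = 1e-9)
  set.seed(10)
  s <- sinuosity(runif(20, 0, 10), runif(20, -50, -40))
  expect_true(s >= 0 && s <= 1)
  expect_error(sinuosity(1:2, 1:2), "at least 3")
})

test_that("daily distance excludes long gaps from both numerator and denominator", {
  tr <- straight_track(n_fix = 40, step_km = 50, interval_h = 6)  # 200 km/day
  fx <- tr$fixes
  keep <- !(seq_len(40) %in% 15:24)  # cut a 60-hour hole
  ddt <- daily_distance(fx$time[keep], fx$lon[keep], fx$lat[keep])
  expect_equal(ddt, 200, tolerance = 1e-9)
  # all gaps too long: reasoned NA
  expect_true(is.na(daily_distance(fx$time[c(1, 20)], fx$lon[c(1, 20)],
                                   fx$lat[c(1, 20)], max_gap_hours = 36)))
})

test_that("departure bearing is taken at the 100 km crossing", {
  tr <- straight_track(n_fix = 30, step_km = 30, bearing = 1.1)
  b <- departure_bearing(tr)  # first fix >= 100 km is 120 km out
  expect_equal(b, initial_bearing(tr$colony[["lon"]], tr$colony[["lat"]],
                                  tr$fixes$lon[5], tr$fixes$lat[5]))
  expect_equal(b, 1.1, tolerance = 0.01)
  near <- straight_track(n_fix = 5, step_km = 10)
  expect_true(is.na(departure_bearing(near)))
})

test_that("month bearings use the rhumb line within a day tolerance", {
  tr <- straight_track(n_fix = 271, step_km = 25, interval_h = 8)  # 90 days
  b2 <- bearing_at_month(tr, 2)
  s <- compute_nsd(tr)
  i <- which.min(abs(s$t - 60))
  expect_equal(b2, rhumb_bearing(s$origin[["lon"]], s$origin[["lat"]],
                                 s$lon[i], s$lat[i]))
  expect_error(bearing_at_month(tr, 1), "month")
  short <- straight_track(n_fix = 20)
  expect_true(is.na(bearing_at_month(short, 3)))
})

test_that("circular summaries recover a concentrated mean direction and full range", {
  a <- c(0.28, 0.31, 0.30, 0.33, 0.29)
  cs <- circular_summary(a)
  expect_equal(cs$mean_direction, mean(a), tolerance = 1e-3)
  expect_gt(cs$R, 0.99)
  expect_lt(cs$rayleigh_p, 0.01)
  expect_lt(cs$angular_range, 0.1)
  # angles wrapping zero average to zero, not pi
  cz <- circular_summary(c(2 * pi - 0.1, 0.1))
  expect_lt(min(cz$mean_direction, 2 * pi - cz$mean_direction), 1e-9)
  # four cardinal directions: zero resultant, full angular range
  cu <- circular_summary(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(cu$R, 0, tolerance = 1e-12)
  expect_equal(cu$angular_range, 3 * pi / 2)
  expect_equal(cu$rayleigh_Z, 0, tolerance = 1e-12)
})

test_that("monthly mean latitude averages the fixes of each 30-day block", {
  tr <- straight_track(n_fix = 200, step_km = 25, interval_h = 12, bearing = 0)
  s <- compute_nsd(tr)
  expect_equal(mean_latitude(tr, 2), mean(s$lat[s$t >= 30 & s$t < 60]))
  expect_gt(mean_latitude(tr, 3), mean_latitude(tr, 1))  # heading north
  expect_true(is.na(mean_latitude(straight_track(n_fix = 10), 3)))
})

test_that("per-period statistics table has one row per track and period", {
  trs <- list(a = straight_track(n_fix = 200, step_km = 25, interval_h = 12,
                                 id = "a"),
              b = straight_track(n_fix = 200, step_km = 30, interval_h = 12,
                                 bearing = 2, id = "b"))
  tab <- period_stats_table(trs)
  expect_identical(nrow(tab), 12L)
  expect_identical(tab$period_index, rep(1:6, 2))
  expect_identical(unique(tab$individual_id), c("a", "b"))
  full <- tab$n_fixes >= 3
  expect_true(all(tab$sinuosity[full] < 1e-6))  # straight tracks
  expect_equal(tab$ddt[tab$individual_id == "a" & full][1], 50, tolerance = 1e-9)
})
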