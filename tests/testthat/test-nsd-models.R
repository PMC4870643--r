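test_that("model curves start at zero and respect parameter counts", {
  t <- seq(0, 90, by = 1)
  hr <- eval_nsd_model("home_range", list(kappa = 1e5, tau = 10), t)
  expect_equal(hr[1], 0)
  expect_true(all(diff(hr) > 0))
  expect_lt(max(hr), 1e5)
  expect_error(eval_nsd_model("migration",
                              list(delta = 1, theta = 50, phi = 2,
                                   theta2 = 40, phi2 = 2), t),
               "theta2")
  expect_identical(vapply(nsd_model_names(), nsd_model_npar, numeric(1)),
                   c(home_range = 2, nomad = 1, half_migration = 3,
                     migration = 5))
})

test_that("concordance is bounded, symmetric, and penalises scale shifts", {
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50)
  cc <- concordance(x, y)
  expect_true(cc >= -1 && cc <= 1)
  expect_equal(concordance(x, y), concordance(y, x))
  expect_equal(concordance(x, x), 1)
  expect_lt(concordance(x, 2 * x), 1)
  expect_lt(concordance(x, x + 1), 1)
})

test_that("with_seed restores the caller's random-number state", {
  set.seed(99)
  before <- .Random.seed
  a <- with_seed(5, runif(3))
  expect_identical(.Random.seed, before)
  expect_identical(a, with_seed(5, runif(3)))
})

test_that("each model is recovered from its own noiseless curve", {
  pars <- list(
    home_range = list(kappa = 1.2e5, tau = 8),
    nomad = list(beta = 5e4),
    half_migration = list(delta = 1.6e7, theta = 20, phi = 3),
    migration = list(delta = 1.6e7, theta = 20, phi = 3, theta2 = 70, phi2 = 4))
  for (m in names(pars)) {
    f <- fit_nsd_model(model_series(m, pars[[m]]), m, seed = 1)
    expect_true(f$converged)
    expect_gt(f$cc, 0.99999)
    rel <- abs(unlist(f$params) - unlist(pars[[m]])) / abs(unlist(pars[[m]]))
    expect_lt(max(rel), 1e-3)
  }
})

test_that("a fitted transition placed beyond the track is implausible", {
  s <- model_series("half_migration", list(delta = 1e6, theta = 20, phi = 3))
  ok <- stub_fit("half_migration", 0.9)
  ok$params <- list(delta = 1e6, theta = 20, phi = 3)
  expect_true(plausibility_check(ok, s))
  late <- ok; late$params$theta <- 140          # theta outside 1.5 * duration
  expect_false(plausibility_check(late, s))
  unobserved <- ok; unobserved$params$theta <- 85  # theta + 2*phi > duration
  expect_false(plausibility_check(unobserved, s))
  too_far <- ok; too_far$params$delta <- (1.3 * max(s$dist))^2
  expect_false(plausibility_check(too_far, s))
  slow <- ok; slow$params$phi <- 120            # timescale beyond duration
  expect_false(plausibility_check(slow, s))
  nofit <- ok; nofit$converged <- FALSE
  expect_false(plausibility_check(nofit, s))
})

test_that("a nomad slope implying a physically impossible range is implausible", {
  s <- model_series("nomad", list(beta = 1e4))
  ok <- stub_fit("nomad", 0.9); ok$params <- list(beta = 1e4)
  expect_true(plausibility_check(ok, s))
  wild <- ok; wild$params$beta <- (41000^2) / 90
  expect_false(plausibility_check(wild, s))
})

test_that("a claimed settlement over still-growing displacement is implausible", {
  # quadratic (ballistic) NSD: a logistic whose plateau covers a growing tail
  t <- seq(0, 90, by = 0.5)
  s <- structure(list(t = t, nsd = (300 * t)^2, dist = 300 * t),
                 class = "nsd_series")
  fake <- stub_fit("half_migration", 0.95)
  fake$params <- list(delta = mean((300 * t[t > 55])^2), theta = 50, phi = 2.5)
  expect_false(plausibility_check(fake, s))
})

test_that("a migration fit is implausible when the bird is manifestly not back", {
  s <- model_series("half_migration", list(delta = 1e6, theta = 15, phi = 2))
  fake <- stub_fit("migration", 0.9)
  fake$params <- list(delta = 1e6, theta = 15, phi = 2, theta2 = 60, phi2 = 3)
  # observed NSD stays at the asymptote after the claimed return at day 60
  expect_false(plausibility_check(fake, s))
  back <- model_series("migration",
                       list(delta = 1e6, theta = 15, phi = 2,
                            theta2 = 60, phi2 = 3))
  expect_true(plausibility_check(fake, back))
})

test_that("selection prefers plausible fits, then concordance, then parsimony", {
  a <- stub_fit("migration", 0.95, plausible = FALSE)
  b <- stub_fit("half_migration", 0.80)
  c <- stub_fit("nomad", 0.70)
  expect_identical(select_model(list(a, b, c))$model, "half_migration")
  # exact concordance tie: fewer parameters win, in any input order
  d <- stub_fit("home_range", 0.80)
  e <- stub_fit("nomad", 0.80)
  expect_identical(select_model(list(b, d, e))$model, "nomad")
  expect_identical(select_model(list(e, b, d))$model, "nomad")
  # nothing plausible: fall back to the best overall
  f <- stub_fit("migration", 0.4, plausible = FALSE)
  g <- stub_fit("nomad", 0.2, plausible = FALSE)
  pick <- select_model(list(g, f))
  expect_identical(pick$model, "migration")
  expect_false(pick$plausible)
})

test_that("the looping detector needs both an NSD decline and consistent rotation", {
  # orbiting track with radius modulation: decline + monotone winding
  loop <- orbit_track(radius_wobble_km = 150)
  expect_true(detect_looping(loop))
  # same circuit at constant radius: no NSD decline
  flat <- orbit_track(radius_wobble_km = 0)
  expect_false(detect_looping(flat))
  # radial out-and-back: a large decline but no net rotation
  out <- destination_point(52.4, -46.2, pi / 4, c(seq(0, 2000, by = 100),
                                                  seq(1900, 0, by = -100)))
  radial <- make_track("radial", "SIM", "juvenile", c(lon = 52.4, lat = -46.2),
                       time = utc_hours(length(out$lon), interval_h = 24),
                       lon = out$lon, lat = out$lat, source = "simulated")
  expect_false(detect_looping(radial))
  # short tracks are never called loops
  expect_false(detect_looping(orbit_track(n_fix = 40, radius_wobble_km = 150)))
})

test_that("movement scales split at 3000 and 6000 km", {
  expect_identical(classify_scale(c(0, 2999.9, 3000, 6000, 6000.1)),
                   c("small", "small", "medium", "medium", "large"))
  expect_true(is.na(classify_scale(NA_real_)))
  expect_error(classify_scale(-5), "non-negative")
})

test_that("dispersion distance is the asymptote root for migration-family fits only", {
  f <- stub_fit("half_migration", 0.9); f$params <- list(delta = 2.5e7)
  expect_equal(dispersion_distance(f), 5000)
  h <- stub_fit("home_range", 0.9)
  expect_true(is.na(dispersion_distance(h)))
  expect_identical(attr(dispersion_distance(h), "reason"), "not_applicable")
})

test_that("degenerate tracks classify to a reasoned NA instead of failing", {
  tr <- straight_track(n_fix = 5)
  cl <- classify_movement(tr)
  expect_true(is.na(cl$movement_type))
  expect_identical(cl$note, "degenerate_track")
})

test_that("classification output is tabulated one row per individual", {
  trs <- list(simulate_track(default_sim_config("half_migration", seed = 3)),
              simulate_track(default_sim_config("nomad", seed = 4)))
  cls <- lapply(trs, classify_movement, seed = 1)
  tab <- classification_table(cls)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("id", "best_model", "movement_type", "cc_home_range",
                    "cc_migration", "range_3mo_km", "scale", "looping",
                    "partial", "plausible") %in% names(tab)))
  expect_identical(tab$movement_type, c("half_migration", "nomad"))
  expect_false(any(tab$partial))
})
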