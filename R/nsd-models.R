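#' NSD movement-mode models
#'
#' Functional forms for the expected net squared displacement (km^2) of the
#' four canonical large-scale movement modes:
#' \describe{
#'   \item{home_range}{saturating residence around the colony,
#'     `kappa * (1 - exp(-t / tau))`}
#'   \item{nomad}{diffusive wandering with NSD linear in time, `beta * t`}
#'   \item{half_migration}{a single logistic: directed transit then settlement
#'     at an asymptote `delta`, without a return leg,
#'     `delta / (1 + exp((theta - t) / phi))`}
#'   \item{migration}{a double logistic: outbound transit, plateau, and return,
#'     `delta/(1+exp((theta-t)/phi)) - delta/(1+exp((theta2-t)/phi2))`,
#'     with `theta2 > theta`}
#' }
#' Parameters: `delta`, `kappa` asymptotic NSD (km^2); `theta`, `theta2`
#' inflection times (days); `phi`, `phi2`, `tau` timescales (days); `beta`
#' NSD slope (km^2/day).
#'
#' @param model one of `"home_range"`, `"nomad"`, `"half_migration"`,
#'   `"migration"`.
#' @param params named list/vector of parameters for the model.
#' @param t time since departure, days (vector).
#' @return expected NSD, km^2.
#' @export
eval_nsd_model <- function(model, params, t) {
  model <- match.arg(model, nsd_model_names())
  p <- as.list(params)
  switch(model,
    home_range = p$kappa * (1 - exp(-t / p$tau)),
    nomad = p$beta * t,
    half_migration = p$delta * stats::plogis((t - p$theta) / p$phi),
    migration = {
      if (p$theta2 <= p$theta) {
        stop("migration model requires theta2 > theta", call. = FALSE)
      }
      p$delta * stats::plogis((t - p$theta) / p$phi) -
        p$delta * stats::plogis((t - p$theta2) / p$phi2)
    })
}

#' @rdname eval_nsd_model
#' @export
nsd_model_names <- function() c("home_range", "nomad", "half_migration", "migration")

# number of free parameters, used by the parsimony tie-break
nsd_model_npar <- function(model) {
  c(home_range = 2, nomad = 1, half_migration = 3, migration = 5)[[model]]
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between observed and predicted values, penalising both
#' imprecision and location/scale shift:
#' `cc = 2*cov(o,p) / (var(o) + var(p) + (mean(o) - mean(p))^2)`,
#' with population (1/n) moments. Used as the goodness-of-fit criterion for
#' NSD model selection. By convention, two constant inputs give 1 when their
#' means are equal and 0 otherwise.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2), finite.
#' @return concordance in `[-1, 1]`.
#' @export
concordance <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("concordance requires finite inputs", call. = FALSE)
  }
  n <- length(observed)
  mo <- mean(observed); mp <- mean(predicted)
  vo <- mean((observed - mo)^2); vp <- mean((predicted - mp)^2)
  cv <- mean((observed - mo) * (predicted - mp))
  denom <- vo + vp + (mo - mp)^2
  if (denom == 0) return(1)  # both constant, equal means
  2 * cv / denom
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# quantile-derived starting values for each model
nsd_start_values <- function(series, model) {
  t <- series$t; y <- series$nsd
  dur <- max(t)
  q90 <- unname(stats::quantile(y, 0.9))
  half <- q90 / 2
  theta0 <- t[which(y >= half)[1]]
  if (is.na(theta0)) theta0 <- dur / 2
  th2 <- t[rev(which(y >= half))[1]]
  if (is.na(th2) || th2 <= theta0) th2 <- min(theta0 + dur / 4, dur)
  switch(model,
    home_range = {
      tau0 <- t[which(y >= 0.63 * q90)[1]]
      if (is.na(tau0) || tau0 <= 0) tau0 <- dur / 5
      list(kappa = max(q90, 1), tau = tau0)
    },
    nomad = list(beta = max(sum(t * y) / max(sum(t^2), 1e-9), 1e-9)),
    half_migration = list(delta = max(q90, 1), theta = theta0,
                          phi = max(dur / 10, 0.5)),
    migration = list(delta = max(q90, 1), theta = theta0,
                     phi = max(dur / 10, 0.5),
                     dtheta = max(th2 - theta0, 1),
                     phi2 = max(dur / 10, 0.5)))
}

nsd_fit_bounds <- function(model) {
  switch(model,
    home_range = list(lower = c(kappa = 0, tau = 1e-2),
                      upper = c(kappa = Inf, tau = Inf)),
    half_migration = list(lower = c(delta = 0, theta = -Inf, phi = 1e-2),
                          upper = c(delta = Inf, theta = Inf, phi = Inf)),
    migration = list(lower = c(delta = 0, theta = -Inf, phi = 1e-2,
                               dtheta = 1e-2, phi2 = 1e-2),
                     upper = c(delta = Inf, theta = Inf, phi = Inf,
                               dtheta = Inf, phi2 = Inf)))
}

nsd_fit_formula <- function(model) {
  switch(model,
    home_range = nsd ~ kappa * (1 - exp(-t / tau)),
    half_migration = nsd ~ delta * plogis((t - theta) / phi),
    migration = nsd ~ delta * (plogis((t - theta) / phi) -
                                 plogis((t - theta - dtheta) / phi2)))
}

#' Fit an NSD movement-mode model to a displacement series
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) with multi-start: a quantile-derived heuristic start plus
#' seeded jittered restarts; the best weighted SSE wins. Residuals are
#' weighted by `1 / max(nsd, 1)` to tame the quadratic (km^2) scale. The
#' nomad (linear) model has a closed-form weighted solution. Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param series an `nsd_series` (see [compute_nsd()]).
#' @param model model name, see [eval_nsd_model()].
#' @param seed integer seed for the jittered restarts.
#' @param n_starts number of starts (1 heuristic + `n_starts - 1` jitters).
#' @return object of class `nsd_fit`: list with `model`, `params` (named),
#'   `cc` (concordance of fitted vs observed; `-Inf` if no start converged),
#'   `converged`, `plausible` (filled by [plausibility_check()]),
#'   `residual_sd` (km^2), `fitted`, `sse`.
#' @export
fit_nsd_model <- function(series, model, seed = 1L, n_starts = 5L) {
  model <- match.arg(model, nsd_model_names())
  t <- series$t; y <- series$nsd
  if (length(t) < 8) stop("need at least 8 NSD points", call. = FALSE)
  if (max(t) < 20) stop("need at least 20 days of data", call. = FALSE)
  w <- 1 / pmax(y, 1)

  failed <- function() {
    structure(list(model = model, params = NULL, cc = -Inf, converged = FALSE,
                   plausible = NA, residual_sd = NA_real_, fitted = NULL,
                   sse = Inf),
              class = "nsd_fit")
  }

  if (model == "nomad") {
    beta <- sum(w * t * y) / sum(w * t^2)
    beta <- max(beta, 0)
    fitted <- beta * t
    return(structure(list(model = model, params = c(beta = beta),
                          cc = concordance(y, fitted), converged = TRUE,
                          plausible = NA,
                          residual_sd = stats::sd(y - fitted),
                          fitted = fitted, sse = sum(w * (y - fitted)^2)),
                     class = "nsd_fit"))
  }

  start0 <- nsd_start_values(series, model)
  bounds <- nsd_fit_bounds(model)
  starts <- list(start0)
  if (n_starts > 1) {
    jit <- with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(k) {
        s <- start0
        for (nm in names(s)) {
          if (nm %in% c("theta")) {
            s[[nm]] <- s[[nm]] + stats::rnorm(1, 0, max(max(series$t) / 8, 1))
          } else {
            s[[nm]] <- s[[nm]] * stats::rlnorm(1, 0, 0.4)
          }
        }
        s
      })
    })
    starts <- c(starts, jit)
  }

  dat <- data.frame(t = t, nsd = y)
  fml <- nsd_fit_formula(model)
  environment(fml) <- environment()  # so nlsLM finds the weights vector
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fml, data = dat, start = s, weights = w,
        lower = bounds$lower[names(s)], upper = bounds$upper[names(s)],
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    pr <- as.numeric(stats::predict(fit, newdata = dat))
    sse <- sum(w * (y - pr)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(fit = fit, sse = sse, pred = pr)
    }
  }
  if (is.null(best)) return(failed())
  params <- stats::coef(best$fit)
  if (model == "migration") {
    params <- c(delta = unname(params[["delta"]]), theta = unname(params[["theta"]]),
                phi = unname(params[["phi"]]),
                theta2 = unname(params[["theta"]] + params[["dtheta"]]),
                phi2 = unname(params[["phi2"]]))
  }
  structure(list(model = model, params = params,
                 cc = concordance(y, best$pred), converged = TRUE,
                 plausible = NA, residual_sd = stats::sd(y - best$pred),
                 fitted = best$pred, sse = best$sse),
            class = "nsd_fit")
}

#' @export
print.nsd_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<nsd_fit> %s: did not converge\n", x$model))
  } else {
    cat(sprintf("<nsd_fit> %s: cc = %.4f, plausible = %s\n  params: %s\n",
                x$model, x$cc, as.character(x$plausible),
                paste(sprintf("%s = %.4g", names(x$params), x$params),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Parameter-plausibility screen for an NSD fit
#'
#' A fitted model is discarded (flagged implausible) when its estimated
#' parameters are inconsistent with the spatio-temporal scales of the
#' trajectory:
#' \itemize{
#'   \item an inflection time `theta` (or `theta2`) outside
#'     `[0, 1.5 * duration]`;
#'   \item an asymptotic distance `sqrt(delta)` or `sqrt(kappa)` exceeding
#'     1.25x the maximum observed colony distance;
#'   \item a timescale (`phi`, `phi2`, `tau`) longer than the track duration;
#'   \item a nomad slope `beta` implying a 3-month displacement beyond
#'     40000 km;
#'   \item a migration-family fit whose settlement is not observed within the
#'     track (`theta + 2*phi > duration`), or a migration fit whose return is
#'     not observed (`theta2 + 2*phi2 > duration`): a logistic transition
#'     placed beyond the data is a claim the trajectory cannot support (and
#'     is how an unbounded nomadic displacement masquerades as a
#'     half-migration, or a half-migration as a migration);
#'   \item a settled phase that is not actually settled: over the fitted
#'     plateau (`theta + 2*phi` to `theta2 - 2*phi2`, or the track end for a
#'     half-migration), the least-squares trend of the observed NSD projects
#'     a change of more than half the asymptote `delta` across the window —
#'     the bird is still in transit where the model claims residency;
#'   \item a migration fit claiming a completed return while the observed NSD
#'     after the fitted return (`t > theta2 + 2*phi2`) still averages more
#'     than 25\% of the asymptote `delta` (the bird is manifestly not back).
#' }
#'
#' @param fit an `nsd_fit`.
#' @param series the `nsd_series` the fit was computed on.
#' @return logical.
#' @export
plausibility_check <- function(fit, series) {
  if (!fit$converged) return(FALSE)
  p <- as.list(fit$params)
  dur <- max(series$t)
  dmax <- sqrt(max(series$nsd))
  ok <- TRUE
  for (nm in intersect(c("theta", "theta2"), names(p))) {
    if (p[[nm]] < 0 || p[[nm]] > 1.5 * dur) ok <- FALSE
  }
  for (nm in intersect(c("delta", "kappa"), names(p))) {
    if (sqrt(p[[nm]]) > 1.25 * dmax) ok <- FALSE
  }
  for (nm in intersect(c("phi", "phi2", "tau"), names(p))) {
    if (p[[nm]] > dur) ok <- FALSE
  }
  if (!is.null(p$beta) && sqrt(p$beta * 90) > 40000) ok <- FALSE
  if (fit$model %in% c("half_migration", "migration") && ok) {
    if (p$theta + 2 * p$phi > dur) ok <- FALSE
    if (fit$model == "migration" && p$theta2 + 2 * p$phi2 > dur) ok <- FALSE
  }
  if (fit$model %in% c("half_migration", "migration") && ok) {
    lo <- p$theta + 2 * p$phi
    hi <- if (fit$model == "migration") p$theta2 - 2 * p$phi2 else dur
    idx <- series$t >= lo & series$t <= hi
    if (sum(idx) >= 5 && hi > lo) {
      slope <- stats::coef(stats::lm(series$nsd[idx] ~ series$t[idx]))[2]
      if (is.finite(slope) && abs(slope) * (hi - lo) > 0.5 * p$delta) ok <- FALSE
    }
  }
  if (fit$model == "migration" && ok) {
    post <- series$t > p$theta2 + 2 * p$phi2
    if (any(post) && mean(series$nsd[post]) > 0.25 * p$delta) ok <- FALSE
  }
  ok
}

#' Select the best-supported NSD model
#'
#' Highest concordance among plausible fits; when no fit is plausible, the
#' highest-concordance fit overall is returned with `plausible = FALSE`
#' propagated. Concordance ties (difference < 1e-6) are broken in favour of
#' the model with fewer parameters. Invariant to the input order.
#'
#' @param fits list of `nsd_fit` objects (with `plausible` filled in).
#' @return the selected `nsd_fit`.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  pl <- vapply(fits, function(f) isTRUE(f$plausible), logical(1))
  pool <- if (any(pl)) fits[pl] else fits
  cc <- vapply(pool, function(f) f$cc, numeric(1))
  np <- vapply(pool, function(f) nsd_model_npar(f$model), numeric(1))
  best_cc <- max(cc)
  tied <- which(cc >= best_cc - 1e-6)
  # among tied fits prefer the most parsimonious model
  winner <- tied[which.min(np[tied])]
  pool[[winner]]
}

#' Detect large-scale looping movements
#'
#' Looping birds stay within a bounded range of the colony while making wide
#' circuits, producing a non-monotone NSD. The detector requires both:
#' \enumerate{
#'   \item a decline in (5-day block-median smoothed) NSD of at least
#'     `decline_frac` of the running maximum, and
#'   \item a consistent rotation of the colony-to-bird bearing: the net
#'     unwrapped bearing sweep over the track is at least `min_sweep` radians
#'     and accounts for at least `min_consistency` of the total absolute
#'     rotation. Bearings are evaluated on fixes at least `min_radius_km`
#'     from the colony, where they are well defined.
#' }
#'
#' @param track a track object.
#' @param series optional precomputed `nsd_series`.
#' @param decline_frac required NSD decline, as a fraction of the running
#'   maximum (default 0.25).
#' @param min_sweep required net bearing sweep, radians (default `pi`).
#' @param min_consistency required ratio of net to total rotation
#'   (default 0.5).
#' @param min_radius_km fixes closer to the colony are skipped (default 100).
#' @param min_days minimum data span; shorter tracks return `FALSE`.
#' @return logical.
#' @export
detect_looping <- function(track, series = NULL, decline_frac = 0.25,
                           min_sweep = pi, min_consistency = 0.5,
                           min_radius_km = 100, min_days = 30) {
  if (is.null(series)) series <- compute_nsd(track)
  if (max(series$t) < min_days) return(FALSE)

  # (i) NSD decline on 5-day block medians
  blk <- floor(series$t / 5)
  s <- vapply(split(series$nsd, blk), stats::median, numeric(1))
  if (length(s) >= 2) {
    m <- cummax(s)
    declined <- any(s[-1] <= (1 - decline_frac) * m[-length(m)] & m[-length(m)] > 0)
  } else {
    declined <- FALSE
  }
  if (!declined) return(FALSE)

  # (ii) consistent rotation of the colony bearing
  far <- series$dist >= min_radius_km
  if (sum(far) < 3) return(FALSE)
  b <- initial_bearing(series$origin[["lon"]], series$origin[["lat"]],
                       series$lon[far], series$lat[far])
  dd <- wrap_pi(diff(b))
  net <- sum(dd); total <- sum(abs(dd))
  total > 0 && abs(net) >= min_sweep && abs(net) / total >= min_consistency
}

#' Classify the movement scale from the 3-month range
#'
#' Small-scale movements stay within 3000 km of the colony; medium-scale
#' dispersal reaches 3000-6000 km; large-scale movements go beyond 6000 km.
#'
#' @param range_km distance from the colony at 3 months, km (vectorised).
#' @param bounds_km c(small/medium, medium/large) class boundaries, km.
#' @return character: "small", "medium" or "large" (`NA` preserved).
#' @export
classify_scale <- function(range_km, bounds_km = c(3000, 6000)) {
  if (any(range_km < 0, na.rm = TRUE)) stop("range must be non-negative", call. = FALSE)
  ifelse(range_km < bounds_km[1], "small",
         ifelse(range_km <= bounds_km[2], "medium", "large"))
}

#' Dispersion distance of a migration-family fit
#'
#' The distance from the colony of the migratory asymptote, `sqrt(delta)`.
#'
#' @param fit an `nsd_fit` for the half-migration or migration model.
#' @return km; `NA_real_` (with attribute `reason`) for other models.
#' @export
dispersion_distance <- function(fit) {
  if (!fit$model %in% c("half_migration", "migration") || !fit$converged) {
    return(structure(NA_real_, reason = "not_applicable"))
  }
  sqrt(fit$params[["delta"]])
}

#' Variation around the migratory asymptote
#'
#' Standard deviation, in km, of `sqrt(nsd) - sqrt(fitted)` over the plateau
#' phase: `t` between `theta + 2*phi` and `theta2 - 2*phi2` (or the end of
#' the series for the half-migration model).
#'
#' @param fit a migration-family `nsd_fit`.
#' @param series the `nsd_series` the fit was computed on.
#' @return km; `NA_real_` with attribute `reason` when the plateau window is
#'   empty or the model is not migration-family.
#' @export
asymptote_variation <- function(fit, series) {
  if (!fit$model %in% c("half_migration", "migration") || !fit$converged) {
    return(structure(NA_real_, reason = "not_applicable"))
  }
  p <- as.list(fit$params)
  lo <- p$theta + 2 * p$phi
  hi <- if (fit$model == "migration") p$theta2 - 2 * p$phi2 else max(series$t)
  sel <- series$t >= lo & series$t <= hi
  if (sum(sel) < 2) return(structure(NA_real_, reason = "empty_plateau"))
  pred <- eval_nsd_model(fit$model, fit$params, series$t[sel])
  stats::sd(sqrt(series$nsd[sel]) - sqrt(pmax(pred, 0)))
}

#' Classify the large-scale movement mode of a track
#'
#' Fits all four NSD models, screens each for parameter plausibility, selects
#' the best-supported model by concordance, and applies the post-hoc looping
#' override: when the looping detector fires and the 3-month range is below
#' `looping_max_range_km`, the movement type is reported as
#' `"large_scale_looping"` (the selected NSD model is still recorded in
#' `best_model`; repeated circuits defeat every model in the family, so the
#' override does not condition on which of them fitted least badly). The
#' movement scale is attached from the 3-month range. Tracks shorter than 80
#' days are flagged as partial classifications.
#'
#' Model fitting uses the winding-aware unwrapped displacement
#' (`compute_nsd(..., unwrap = TRUE)`): for circumpolar movements the
#' great-circle beeline folds back on itself and the NSD of a steadily
#' travelling nomad would be non-monotone, whereas the unwrapped displacement
#' keeps growing, which is the behaviour the model family describes. The
#' 3-month range and the looping detector remain great-circle based.
#'
#' @param track a track object.
#' @param seed seed for the fit restarts.
#' @param looping_max_range_km range ceiling for the looping override
#'   (default 3500 km).
#' @return object of class `movement_classification`.
#' @export
classify_movement <- function(track, seed = 1L, looping_max_range_km = 3500) {
  series <- tryCatch(compute_nsd(track, unwrap = TRUE), error = function(e) NULL)
  fail <- function(note) {
    structure(list(id = track$id, species = track$species,
                   best_model = NA_character_, movement_type = NA_character_,
                   cc = stats::setNames(rep(NA_real_, 4), nsd_model_names()),
                   params = NULL, range_3mo = NA_real_, scale = NA_character_,
                   dispersion_distance = NA_real_,
                   asymptote_variation = NA_real_,
                   looping = NA, partial = NA, plausible = NA, note = note,
                   fits = NULL),
              class = "movement_classification")
  }
  if (is.null(series) || length(series$t) < 8 || max(series$t) < 20) {
    return(fail("degenerate_track"))
  }
  duration <- max(series$t)
  fits <- lapply(nsd_model_names(), function(m) {
    f <- tryCatch(fit_nsd_model(series, m, seed = seed), error = function(e) NULL)
    if (is.null(f)) {
      f <- structure(list(model = m, params = NULL, cc = -Inf, converged = FALSE,
                          plausible = FALSE, residual_sd = NA_real_,
                          fitted = NULL, sse = Inf), class = "nsd_fit")
    } else {
      f$plausible <- plausibility_check(f, series)
    }
    f
  })
  names(fits) <- nsd_model_names()
  if (all(vapply(fits, function(f) !f$converged, logical(1)))) {
    return(fail("no_model_converged"))
  }
  best <- select_model(fits)
  range_3mo <- range_at(track, 90)
  looping <- detect_looping(track)  # great-circle series, not the unwrapped one
  movement_type <- best$model
  if (isTRUE(looping) && !is.na(range_3mo) && range_3mo < looping_max_range_km) {
    movement_type <- "large_scale_looping"
  }
  structure(
    list(id = track$id, species = track$species,
         best_model = best$model, movement_type = movement_type,
         cc = vapply(fits, function(f) f$cc, numeric(1)),
         params = best$params,
         range_3mo = as.numeric(range_3mo),
         scale = if (is.na(range_3mo)) NA_character_ else classify_scale(range_3mo),
         dispersion_distance = as.numeric(dispersion_distance(best)),
         asymptote_variation = as.numeric(asymptote_variation(best, series)),
         looping = looping,
         partial = duration < 80,
         plausible = isTRUE(best$plausible),
         note = NA_character_,
         fits = fits),
    class = "movement_classification")
}

#' @export
print.movement_classification <- function(x, ...) {
  cat(sprintf("<movement_classification> %s (%s): %s (best NSD model %s, cc %.3f)\n",
              x$id, x$species, x$movement_type, x$best_model,
              x$cc[[x$best_model]]))
  cat(sprintf("  range at 3 months: %.0f km (%s scale)%s\n",
              x$range_3mo, x$scale, if (isTRUE(x$partial)) " [partial track]" else ""))
  invisible(x)
}

#' Tabulate movement classifications
#'
#' @param classifications list of `movement_classification` objects.
#' @return data frame, one row per individual, with per-model concordance
#'   columns, best-fit parameters (JSON), movement type, 3-month range and
#'   scale.
#' @export
classification_table <- function(classifications) {
  rows <- lapply(classifications, function(cl) {
    data.frame(
      id = cl$id, species = cl$species,
      best_model = cl$best_model, movement_type = cl$movement_type,
      cc_home_range = unname(cl$cc[["home_range"]]),
      cc_nomad = unname(cl$cc[["nomad"]]),
      cc_half_migration = unname(cl$cc[["half_migration"]]),
      cc_migration = unname(cl$cc[["migration"]]),
      params = if (is.null(cl$params)) NA_character_ else
        as.character(jsonlite::toJSON(as.list(cl$params), auto_unbox = TRUE, digits = 8)),
      range_3mo_km = cl$range_3mo, scale = cl$scale,
      looping = cl$looping, partial = cl$partial, plausible = cl$plausible,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
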