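#' Build a run configuration
#'
#' All analysis constants live here as named keys so a run is fully described
#' by its configuration (echoed into the output manifest).
#'
#' @param input path to a track file (see [read_tracks()]); `NULL` simulates a
#'   cohort instead.
#' @param colonies path to a CSV with columns `id, lon, lat`, or `NULL`.
#' @param n_per_mode cohort size per movement mode when simulating.
#' @param modes movement modes to simulate.
#' @param vmax_kmh speed-filter ceiling, km/h.
#' @param departure_km radius defining the departure fix, km.
#' @param departure_bearing_km radius for the departure bearing, km.
#' @param scale_bounds_km movement-scale class boundaries, km.
#' @param habitat_threshold_m neritic/oceanic depth boundary, m.
#' @param max_gap_hours longest usable inter-fix gap for DDT, hours.
#' @param period_days period length for trajectory statistics, days.
#' @param looping_max_range_km range ceiling for the looping override, km.
#' @param synthetic_rasters logical; generate synthetic environmental rasters
#'   for habitat annotation.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, colonies = NULL,
                       n_per_mode = 5,
                       modes = c("home_range", "nomad", "half_migration",
                                 "migration", "looping"),
                       vmax_kmh = 90, departure_km = 5,
                       departure_bearing_km = 100,
                       scale_bounds_km = c(3000, 6000),
                       habitat_threshold_m = -3000,
                       max_gap_hours = 36, period_days = 15,
                       looping_max_range_km = 3500,
                       synthetic_rasters = TRUE,
                       seed = 1L, out_dir = "fledgemove_out") {
  stopifnot(vmax_kmh > 0, departure_km > 0, period_days > 0,
            scale_bounds_km[1] < scale_bounds_km[2])
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a key=value text file
#'
#' Unknown keys raise an error; values are coerced to the type of the
#' corresponding [run_config()] default. Comma-separated values become
#' vectors. Lines starting with `#` are comments.
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  defaults <- run_config()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("unknown config key: ", key, call. = FALSE)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    d <- defaults[[key]]
    args[[key]] <- if (is.numeric(d) || is.null(d) && key %in% c("seed")) {
      as.numeric(parts)
    } else if (is.logical(d)) {
      as.logical(parts)
    } else {
      parts
    }
  }
  do.call(run_config, args)
}

#' Run the full dispersal analysis pipeline
#'
#' read (or simulate) -> speed-filter -> NSD classification -> per-period
#' trajectory statistics -> circular summaries -> habitat annotation ->
#' between-species comparisons. Writes delimited tables and a JSON run
#' manifest (configuration echo, seed, stage counts) into `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `classification`, `period_stats`,
#'   `circular`, `habitat`, `contrasts`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("fledgemove")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")],
                   stages = list())

  # stage 1: acquire tracks
  if (!is.null(config$input)) {
    colonies <- if (!is.null(config$colonies)) {
      utils::read.csv(config$colonies, stringsAsFactors = FALSE)
    } else NULL
    rd <- read_tracks(config$input, colonies = colonies)
    tracks <- rd$tracks
    manifest$stages$read <- unclass(rd$report)
    truth <- NULL
  } else {
    cohort <- simulate_cohort(n_per_mode = config$n_per_mode,
                              seed = config$seed, modes = config$modes)
    tracks <- cohort$tracks
    truth <- cohort$truth
    utils::write.csv(truth, file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE)
    manifest$stages$simulate <- list(n_tracks = length(tracks))
  }
  if (length(tracks) == 0) stop("no input tracks", call. = FALSE)

  # stage 2: speed filter
  n_removed <- 0L
  tracks <- lapply(tracks, function(tr) {
    sf <- speed_filter(tr, vmax = config$vmax_kmh)
    n_removed <<- n_removed + sf$report$n_removed_speed
    sf$track
  })
  manifest$stages$speed_filter <- list(n_tracks = length(tracks),
                                       n_fixes_removed = n_removed)

  # stage 3: NSD classification
  classifications <- lapply(tracks, classify_movement, seed = config$seed,
                            looping_max_range_km = config$looping_max_range_km)
  cls <- classification_table(classifications)
  utils::write.csv(cls, file.path(config$out_dir, "classification.csv"),
                   row.names = FALSE)
  manifest$stages$classification <- list(
    n_tracks = nrow(cls), n_failed = sum(is.na(cls$movement_type)))

  # stage 4: per-period trajectory statistics
  ps <- period_stats_table(tracks, length_days = config$period_days)
  utils::write.csv(ps, file.path(config$out_dir, "period_stats.csv"),
                   row.names = FALSE)
  manifest$stages$period_stats <- list(n_rows = nrow(ps))

  # stage 5: circular summaries per species
  circ <- list()
  for (sp in unique(vapply(tracks, function(t) t$species, ""))) {
    sp_tracks <- Filter(function(t) t$species == sp, tracks)
    dep <- vapply(sp_tracks, departure_bearing,
                  radius_km = config$departure_bearing_km, numeric(1))
    b2 <- vapply(sp_tracks, bearing_at_month, month = 2, numeric(1))
    b3 <- vapply(sp_tracks, bearing_at_month, month = 3, numeric(1))
    circ[[sp]] <- lapply(
      list(departure = dep, month2 = b2, month3 = b3),
      function(a) {
        a <- a[is.finite(a)]
        if (length(a) >= 2) unclass(circular_summary(a)) else NULL
      })
  }
  jsonlite::write_json(circ, file.path(config$out_dir, "circular_summaries.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$stages$circular <- list(n_species = length(circ))

  # stage 6: habitat annotation
  habitat <- NULL
  if (isTRUE(config$synthetic_rasters)) {
    rasters <- make_env_rasters(seed = config$seed)
    habitat <- do.call(rbind, lapply(tracks, function(tr) {
      sh <- settlement_habitat(tr, rasters)
      data.frame(id = tr$id, species = tr$species, habitat = sh$habitat,
                 fraction = sh$fraction, n_classified = sh$n,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(habitat, file.path(config$out_dir, "habitat.csv"),
                     row.names = FALSE)
    manifest$stages$habitat <- list(n_tracks = nrow(habitat))
  }

  # stage 7: group comparisons (needs >= 2 groups with >= 2 individuals)
  contrasts <- NULL
  grp <- if (!is.null(truth)) {
    m <- truth$mode[match(ps$individual_id, truth$id)]
    ifelse(is.na(m), ps$species, m)
  } else ps$species
  ps$group <- grp
  counts <- tapply(ps$individual_id, ps$group, function(x) length(unique(x)))
  if (length(counts) >= 2 && all(counts >= 2)) {
    # seeded: the Tukey adjustment integrates a multivariate normal by
    # quasi-random sampling, so the p-values are only reproducible under a seed
    contrasts <- with_seed(config$seed, {
      do.call(rbind, lapply(c("ddt", "sinuosity"), function(resp) {
        ct <- compare_groups(ps, response = resp, group = "group")
        ct$response <- resp
        ct
      }))
    })
    utils::write.csv(contrasts, file.path(config$out_dir, "contrasts.csv"),
                     row.names = FALSE)
    manifest$stages$comparisons <- list(n_contrasts = nrow(contrasts))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(classification = cls, period_stats = ps, circular = circ,
                 habitat = habitat, contrasts = contrasts,
                 manifest = manifest))
}
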