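#' Construct a track object
#'
#' A track is the unit of analysis: the ordered at-sea fixes of one individual
#' together with its natal colony, species code and age class. Timestamps must
#' be strictly increasing; duplicated timestamps should be removed upstream
#' (see [read_tracks()]).
#'
#' @param id individual identifier.
#' @param species species code (e.g. "WAAL").
#' @param age_class "juvenile" or "adult".
#' @param colony c(lon, lat) of the natal colony, degrees.
#' @param time POSIXct timestamps (UTC).
#' @param lon,lat fix coordinates, degrees.
#' @param lc optional Argos location-class codes.
#' @param source one of "argos", "gls", "simulated".
#' @return object of class `seabird_track`.
#' @export
make_track <- function(id, species, age_class, colony, time, lon, lat,
                       lc = NULL, source = "argos") {
  age_class <- match.arg(age_class, c("juvenile", "adult"))
  source <- match.arg(source, c("argos", "gls", "simulated"))
  stopifnot(length(time) == length(lon), length(lon) == length(lat))
  if (length(time) >= 2 && any(diff(as.numeric(time)) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  check_lat(lat)
  fixes <- data.frame(time = time, lon = normalize_lon(lon), lat = lat)
  fixes$lc <- if (is.null(lc)) NA_character_ else as.character(lc)
  structure(
    list(id = as.character(id), species = as.character(species),
         age_class = age_class,
         colony = c(lon = unname(normalize_lon(colony[["lon"]])),
                    lat = unname(colony[["lat"]])),
         fixes = fixes, source = source),
    class = "seabird_track"
  )
}

#' @export
print.seabird_track <- function(x, ...) {
  cat(sprintf("<seabird_track> %s (%s, %s, %s): %d fixes, %s to %s\n",
              x$id, x$species, x$age_class, x$source, nrow(x$fixes),
              format(min(x$fixes$time)), format(max(x$fixes$time))))
  invisible(x)
}

#' Track duration in days
#' @param track a track object.
#' @return duration in fractional days.
#' @export
track_duration_days <- function(track) {
  as.numeric(difftime(max(track$fixes$time), min(track$fixes$time), units = "days"))
}

new_filter_report <- function(n_input = 0L, n_removed_unparseable = 0L,
                              n_removed_duplicate = 0L, n_removed_speed = 0L) {
  n_output <- n_input - n_removed_unparseable - n_removed_duplicate - n_removed_speed
  structure(list(n_input = n_input,
                 n_removed_unparseable = n_removed_unparseable,
                 n_removed_duplicate = n_removed_duplicate,
                 n_removed_speed = n_removed_speed,
                 n_output = n_output),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> %d in; removed %d unparseable, %d duplicate, %d speed; %d out\n",
    x$n_input, x$n_removed_unparseable, x$n_removed_duplicate,
    x$n_removed_speed, x$n_output))
  invisible(x)
}

#' Read tracks from a delimited text file
#'
#' Reads a UTF-8 comma- or tab-delimited file (delimiter autodetected from the
#' header line) with columns `id, species, age_class, datetime, lon, lat`
#' and optionally `lc`. Datetimes are ISO-8601; UTC is assumed when no zone is
#' given. Rows with unparseable coordinates or timestamps are dropped and
#' counted; rows duplicating an earlier timestamp within an individual are
#' dropped and counted.
#'
#' @param path file path.
#' @param colonies data frame with columns `id`, `lon`, `lat` giving each
#'   individual's natal colony. If `NULL`, the first valid fix of each
#'   individual is used as its colony (with a warning).
#' @param source track source label stored on each track.
#' @return list with `tracks` (named list of track objects) and `report`
#'   (a `filter_report`).
#' @export
read_tracks <- function(path, colonies = NULL, source = "argos") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    warning("empty track file: ", path)
    return(list(tracks = list(), report = new_filter_report()))
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  required <- c("id", "species", "age_class", "datetime", "lon", "lat")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n_input <- nrow(df)
  if (n_input == 0) {
    warning("no data rows in track file: ", path)
    return(list(tracks = list(), report = new_filter_report()))
  }
  time <- parse_datetime_utc(df$datetime)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  ok <- !is.na(time) & !is.na(lon) & !is.na(lat) & abs(lat) <= 90
  n_unparseable <- sum(!ok)
  df <- df[ok, , drop = FALSE]; time <- time[ok]; lon <- lon[ok]; lat <- lat[ok]

  tracks <- list()
  n_dup <- 0L
  for (ind in unique(df$id)) {
    sel <- df$id == ind
    o <- order(time[sel])
    ti <- time[sel][o]; lo <- lon[sel][o]; la <- lat[sel][o]
    lc <- if ("lc" %in% names(df)) df$lc[sel][o] else NULL
    dup <- duplicated(ti)
    n_dup <- n_dup + sum(dup)
    ti <- ti[!dup]; lo <- lo[!dup]; la <- la[!dup]
    if (!is.null(lc)) lc <- lc[!dup]
    if (!is.null(colonies)) {
      row <- colonies[colonies$id == ind, , drop = FALSE]
      if (nrow(row) == 0) stop("no colony given for individual ", ind, call. = FALSE)
      colony <- c(lon = row$lon[1], lat = row$lat[1])
    } else {
      warning("no colony table supplied; using first fix of ", ind, " as colony")
      colony <- c(lon = lo[1], lat = la[1])
    }
    tracks[[ind]] <- make_track(
      id = ind, species = df$species[sel][o][!dup][1],
      age_class = df$age_class[sel][o][!dup][1],
      colony = colony, time = ti, lon = lo, lat = la, lc = lc, source = source)
  }
  report <- new_filter_report(n_input = n_input,
                              n_removed_unparseable = n_unparseable,
                              n_removed_duplicate = n_dup)
  message(sprintf("read %d rows -> %d fixes in %d tracks (%d unparseable, %d duplicates removed)",
                  n_input, report$n_output, length(tracks), n_unparseable, n_dup))
  list(tracks = tracks, report = report)
}

# Parse ISO-8601-style datetimes element-wise, trying each format per row so
# a file can mix formats and carry bad rows without poisoning the good ones.
parse_datetime_utc <- function(x) {
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  todo <- !is.na(x) & nzchar(x)
  for (f in fmts) {
    if (!any(todo)) break
    got <- as.POSIXct(strptime(x[todo], format = f, tz = "UTC"), tz = "UTC")
    out[todo][!is.na(got)] <- got[!is.na(got)]
    todo[todo] <- is.na(got)
  }
  out
}

#' Write tracks to a delimited text file
#'
#' Emits the same dialect [read_tracks()] reads (comma separated, ISO-8601
#' UTC datetimes).
#'
#' @param tracks a track object or list of track objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "seabird_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    data.frame(id = tr$id, species = tr$species, age_class = tr$age_class,
               datetime = format(tr$fixes$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               lon = tr$fixes$lon, lat = tr$fixes$lat, lc = tr$fixes$lc,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Iterative ground-speed filter
#'
#' Removes implausible fixes by iteratively deleting, among fixes touching a
#' ground speed above `vmax`, the one whose slower adjacent segment is
#' fastest, until no speed exceeds `vmax`. A displaced fix forces both of its
#' segments fast, while its innocent neighbours each touch only one fast
#' segment, so scoring each fix by the slower of its two segments singles out
#' the culprit. Deterministic; the colony and metadata are preserved.
#'
#' @param track a track object.
#' @param vmax maximum plausible sustained ground speed, km/h (default 90,
#'   an upper ceiling for procellariiform flight).
#' @return list with `track` (filtered) and `report` (a `filter_report`).
#' @export
speed_filter <- function(track, vmax = 90) {
  stopifnot(vmax > 0)
  fx <- track$fixes
  n_input <- nrow(fx)
  removed <- 0L
  repeat {
    if (nrow(fx) < 2) break
    dt_h <- diff(as.numeric(fx$time)) / 3600
    d_km <- haversine_km(fx$lon[-nrow(fx)], fx$lat[-nrow(fx)],
                         fx$lon[-1], fx$lat[-1])
    sp <- d_km / dt_h
    if (all(sp <= vmax)) break
    # per-fix score: the slower of the (up to two) segments touching the fix
    score <- pmin(c(Inf, sp), c(sp, Inf))
    bad <- which(pmax(c(0, sp), c(sp, 0)) > vmax)
    # never drop the first fix (departure anchor) unless it is the only culprit
    cand <- bad[bad > 1]
    drop <- if (length(cand) > 0) cand[which.max(score[cand])] else bad[which.max(score[bad])]
    fx <- fx[-drop, , drop = FALSE]
    removed <- removed + 1L
  }
  if (nrow(fx) < 2) stop("speed filter removed all fixes", call. = FALSE)
  out <- track
  out$fixes <- fx
  list(track = out,
       report = new_filter_report(n_input = n_input, n_removed_speed = removed))
}

#' Block-average smoothing of a track
#'
#' Averages fixes in consecutive non-overlapping windows of `window_days`
#' days, the standard treatment for coarse geolocator (GLS) positions.
#' Longitudes are unwrapped about the window's first fix before averaging so
#' windows straddling the antimeridian are handled correctly. Each non-empty
#' window emits one fix at the window centre time.
#'
#' @param track a track object.
#' @param window_days window length, days (default 3).
#' @return a smoothed track object.
#' @export
smooth_track <- function(track, window_days = 3) {
  stopifnot(window_days > 0)
  fx <- track$fixes
  t0 <- as.numeric(fx$time[1])
  win <- floor((as.numeric(fx$time) - t0) / (window_days * 86400))
  out <- lapply(split(seq_len(nrow(fx)), win), function(idx) {
    lon <- fx$lon[idx]
    # unwrap about the first fix in the window
    lon <- lon[1] + wrap_pi((lon - lon[1]) * pi / 180) * 180 / pi
    data.frame(time = as.POSIXct((win[idx[1]] + 0.5) * window_days * 86400 + t0,
                                 origin = "1970-01-01", tz = "UTC"),
               lon = normalize_lon(mean(lon)), lat = mean(fx$lat[idx]),
               lc = NA_character_)
  })
  res <- track
  res$fixes <- do.call(rbind, out)
  rownames(res$fixes) <- NULL
  res
}

#' Mean sampling rate of a track
#'
#' @param track a track object.
#' @return locations per day (`n_fixes / duration_days`); `NA` for a
#'   single-fix track.
#' @export
sampling_rate <- function(track) {
  dur <- track_duration_days(track)
  if (nrow(track$fixes) < 2 || dur <= 0) return(NA_real_)
  nrow(track$fixes) / dur
}
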