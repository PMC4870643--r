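#' Construct a gridded environmental raster
#'
#' A regular lon/lat grid of one environmental variable. Values are stored as
#' a matrix with rows indexed by latitude (ascending) and columns by longitude
#' (ascending). Bathymetry follows the oceanographic sign convention: negative
#' below sea level, positive over land.
#'
#' @param variable one of `"bathymetry_m"`, `"sst_c"`, `"chla_mg_m3"`.
#' @param lon,lat cell-centre coordinate vectors, degrees, ascending, regular.
#' @param values matrix `length(lat) x length(lon)`.
#' @param nodata missing-value sentinel (default -9999).
#' @return object of class `env_raster`.
#' @export
env_raster <- function(variable, lon, lat, values, nodata = -9999) {
  variable <- match.arg(variable, c("bathymetry_m", "sst_c", "chla_mg_m3"))
  stopifnot(nrow(values) == length(lat), ncol(values) == length(lon))
  if (length(lon) > 1) stopifnot(diff(range(diff(lon))) < 1e-6, all(diff(lon) > 0))
  if (length(lat) > 1) stopifnot(diff(range(diff(lat))) < 1e-6, all(diff(lat) > 0))
  structure(list(variable = variable, lon = lon, lat = lat,
                 values = values, nodata = nodata),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf("<env_raster> %s: %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
              x$variable, length(x$lat), length(x$lon),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @param variable variable name to attach (see [env_raster()]).
#' @return an `env_raster`.
#' @export
read_ascii_grid <- function(path, variable) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  ncols <- hdr$ncols; nrows <- hdr$nrows
  cell <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner + cell / 2 else hdr$xllcenter
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner + cell / 2 else hdr$yllcenter
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == ncols * nrows)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[nrows:1, , drop = FALSE]  # ASCII grids store north-to-south
  m[m == nodata] <- NA
  env_raster(variable, lon = xll + (seq_len(ncols) - 1) * cell,
             lat = yll + (seq_len(nrows) - 1) * cell, values = m,
             nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param raster an `env_raster`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  cell <- if (length(raster$lon) > 1) raster$lon[2] - raster$lon[1] else 1
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", min(raster$lon) - cell / 2),
    sprintf("yllcorner %.10g", min(raster$lat) - cell / 2),
    sprintf("cellsize %.10g", cell),
    sprintf("NODATA_value %g", raster$nodata)), con)
  for (i in nrow(m):1) {
    writeLines(paste(format(m[i, ], trim = TRUE, scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' Nearest-cell raster lookup
#'
#' Nearest-cell (not interpolated) lookup, matching the coarse accuracy of
#' Argos/GLS locations.
#'
#' @param raster an `env_raster`.
#' @param lon,lat query coordinates, degrees (vectorised).
#' @return numeric vector; `NA` outside the raster extent.
#' @export
raster_lookup <- function(raster, lon, lat) {
  cell <- if (length(raster$lon) > 1) raster$lon[2] - raster$lon[1] else 1
  j <- round((normalize_lon(lon) - raster$lon[1]) / cell) + 1
  i <- round((lat - raster$lat[1]) / cell) + 1
  ok <- i >= 1 & i <= length(raster$lat) & j >= 1 & j <= length(raster$lon)
  out <- rep(NA_real_, length(lon))
  out[ok] <- raster$values[cbind(i[ok], j[ok])]
  out
}

#' Annotate track fixes with environmental values
#'
#' Nearest-cell lookup of each supplied raster at every fix. Fixes outside a
#' raster's extent are reported missing with reason `out_of_extent`; fixes
#' over land (bathymetry > 0) with reason `land`.
#'
#' @param track a track object.
#' @param rasters named list of `env_raster` objects (names are ignored; the
#'   raster's own `variable` field is used).
#' @return data frame with one row per fix: `time`, `lon`, `lat`, one column
#'   per variable, and `missing_reason` (`NA`, `"out_of_extent"` or `"land"`).
#' @export
annotate_track <- function(track, rasters) {
  if (length(rasters) == 0) stop("no rasters supplied", call. = FALSE)
  fx <- track$fixes
  out <- data.frame(time = fx$time, lon = fx$lon, lat = fx$lat)
  for (r in rasters) out[[r$variable]] <- raster_lookup(r, fx$lon, fx$lat)
  reason <- rep(NA_character_, nrow(fx))
  if (!is.null(out$bathymetry_m)) {
    reason[!is.na(out$bathymetry_m) & out$bathymetry_m > 0] <- "land"
    reason[is.na(out$bathymetry_m)] <- "out_of_extent"
  }
  out$missing_reason <- reason
  out
}

#' Classify ocean depth as neritic or oceanic
#'
#' Neritic waters (continental shelf to lower slope) are shallower than
#' 3000 m: `depth > -3000` is neritic, `depth <= -3000` is oceanic (the rule
#' is a strict inequality, so exactly -3000 m is oceanic). Positive depths are
#' land and return `NA`.
#'
#' @param depth_m depth in metres, negative below sea level (vectorised).
#' @param threshold_m neritic/oceanic boundary depth (default -3000 m).
#' @return character vector: `"neritic"`, `"oceanic"`, or `NA` for land.
#' @export
classify_habitat <- function(depth_m, threshold_m = -3000) {
  ifelse(depth_m > 0, NA_character_,
         ifelse(depth_m > threshold_m, "neritic", "oceanic"))
}

#' Habitat of a track's settlement area
#'
#' Classifies the fixes of the final 15-day segment by the neritic/oceanic
#' depth rule and labels the individual with the majority class.
#'
#' @param track a track object.
#' @param rasters list of rasters including a bathymetry raster.
#' @param window_days length of the final segment, days (default 15).
#' @return list with `habitat` (majority class, or `NA` if undetermined),
#'   `fraction` (share of classified fixes in the majority class) and `n`
#'   (number of classified fixes).
#' @export
settlement_habitat <- function(track, rasters, window_days = 15) {
  bathy <- NULL
  for (r in rasters) if (r$variable == "bathymetry_m") bathy <- r
  if (is.null(bathy)) stop("no bathymetry raster supplied", call. = FALSE)
  t_end <- max(as.numeric(track$fixes$time))
  sel <- as.numeric(track$fixes$time) >= t_end - window_days * 86400
  depth <- raster_lookup(bathy, track$fixes$lon[sel], track$fixes$lat[sel])
  cls <- classify_habitat(depth)
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) {
    return(list(habitat = NA_character_, fraction = NA_real_, n = 0L))
  }
  tab <- table(cls)
  list(habitat = names(tab)[which.max(tab)],
       fraction = max(tab) / sum(tab), n = length(cls))
}
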