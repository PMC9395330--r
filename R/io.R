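# ISO-8601-ish UTC parser returning NA (not an error) on bad rows so
# callers can point at the offending line
parse_utc <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' Read fish position fixes from a positioning-system CSV export
#'
#' Reads a table of acoustic-telemetry position estimates with columns
#' \code{fish_id, datetime_utc, easting_m, northing_m, depth_m, hpe}
#' (ISO-8601 timestamps, UTC). The \code{depth_m} column is optional;
#' all other columns are mandatory. Rows that duplicate another row
#' exactly (same fish, time, easting and northing) are dropped with a
#' message reporting the count. Output is grouped by fish and
#' time-sorted within fish.
#'
#' @param path path to the CSV file.
#' @return A data frame of class \code{position_fixes} with columns
#'   \code{fish_id}, \code{t} (POSIXct, UTC), \code{x}, \code{y},
#'   \code{depth} (NA when absent), \code{hpe} and \code{hpe_m}
#'   (NA until calibrated with \code{\link{apply_calibration}}).
#' @seealso \code{\link{apply_calibration}}, \code{\link{filter_positions}}
#' @export
read_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "datetime_utc", "easting_m", "northing_m", "hpe")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("position file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  t <- parse_utc(raw$datetime_utc)
  if (anyNA(t)) {
    bad <- which(is.na(t))[1L]
    stop("unparseable timestamp at data row ", bad, ": ",
         raw$datetime_utc[bad])
  }
  fx <- data.frame(fish_id = as.character(raw$fish_id), t = t,
                   x = as.numeric(raw$easting_m),
                   y = as.numeric(raw$northing_m),
                   depth = if ("depth_m" %in% names(raw))
                     as.numeric(raw$depth_m) else NA_real_,
                   hpe = as.numeric(raw$hpe),
                   hpe_m = NA_real_,
                   stringsAsFactors = FALSE)
  dup <- duplicated(fx[, c("fish_id", "t", "x", "y")])
  if (any(dup)) {
    message("read_positions: dropped ", sum(dup), " exact duplicate fix(es)")
    fx <- fx[!dup, , drop = FALSE]
  }
  fx <- fx[order(fx$fish_id, fx$t), , drop = FALSE]
  rownames(fx) <- NULL
  class(fx) <- c("position_fixes", "data.frame")
  fx
}

#' Write position fixes in the standard CSV dialect
#'
#' @param fixes a \code{position_fixes} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_positions <- function(fixes, path) {
  out <- data.frame(
    fish_id = fixes$fish_id,
    datetime_utc = format(fixes$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    easting_m = fixes$x, northing_m = fixes$y,
    depth_m = fixes$depth, hpe = fixes$hpe)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the station table (reefs and receivers)
#'
#' Stations share one planar easting/northing frame with the position
#' fixes. \code{kind} is \code{"reef"} or \code{"receiver"};
#' \code{surveyed} marks receivers with measured GPS coordinates usable
#' for error calibration.
#'
#' @param path path to a CSV with columns
#'   \code{station_id,kind,easting_m,northing_m,surveyed}.
#' @return data frame with columns \code{station_id}, \code{kind},
#'   \code{x}, \code{y}, \code{surveyed}.
#' @export
read_stations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "kind", "easting_m", "northing_m")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("station file is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$station_id))
    stop("duplicate station_id in station table")
  if (!all(raw$kind %in% c("reef", "receiver")))
    stop("station kind must be 'reef' or 'receiver'")
  data.frame(station_id = as.character(raw$station_id), kind = raw$kind,
             x = as.numeric(raw$easting_m), y = as.numeric(raw$northing_m),
             surveyed = if ("surveyed" %in% names(raw))
               as.logical(raw$surveyed) else raw$kind == "receiver",
             stringsAsFactors = FALSE)
}

#' Write a station table
#' @param stations data frame as returned by \code{\link{read_stations}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_stations <- function(stations, path) {
  utils::write.csv(
    data.frame(station_id = stations$station_id, kind = stations$kind,
               easting_m = stations$x, northing_m = stations$y,
               surveyed = stations$surveyed),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a bathymetry grid
#'
#' A regular raster of seabed depth (m, positive down). Depths are
#' stored as a matrix indexed \code{[i, j]} with \code{i} the column
#' (west to east) and \code{j} the row (south to north); cell centre
#' \code{(i, j)} is at \code{(x0 + (i - 0.5) * cellsize,
#' y0 + (j - 0.5) * cellsize)}.
#'
#' @param x0,y0 coordinates of the lower-left (south-west) grid corner, m.
#' @param cellsize cell edge length, m (> 0).
#' @param depth numeric matrix of seabed depths, dim \code{c(nx, ny)};
#'   NA marks no-data cells.
#' @return object of class \code{bathy_grid}.
#' @export
bathy_grid <- function(x0, y0, cellsize, depth) {
  stopifnot(is.matrix(depth), cellsize > 0)
  structure(list(x0 = x0, y0 = y0, cellsize = cellsize,
                 nx = nrow(depth), ny = ncol(depth), depth = depth),
            class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat("bathy_grid: ", x$nx, "x", x$ny, " cells of ", x$cellsize,
      " m, origin (", x$x0, ", ", x$y0, ")\n", sep = "")
  cat("  depth range: ", paste(signif(range(x$depth, na.rm = TRUE), 4),
                               collapse = " - "), " m (positive down)\n",
      sep = "")
  invisible(x)
}

#' Read an ESRI ASCII bathymetry grid
#'
#' Parses the standard ESRI ASCII raster header (\code{ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value}) followed by row-major
#' values ordered north to south. NODATA cells become NA.
#'
#' @param path path to the .asc file.
#' @return a \code{\link{bathy_grid}}.
#' @export
read_bathymetry <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header; need: ", paste(need, collapse = ", "))
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))))
  vals <- vals[!is.na(vals) | seq_along(vals) <= hdr$ncols * hdr$nrows]
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII value count (", length(vals),
         ") does not match header (", hdr$ncols * hdr$nrows, ")")
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  # values arrive north row first; flip to south-origin [i, j] indexing
  m <- matrix(vals, nrow = hdr$ncols, ncol = hdr$nrows)
  bathy_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
             m[, hdr$nrows:1, drop = FALSE])
}

#' Write a bathymetry grid as ESRI ASCII
#' @param grid a \code{\link{bathy_grid}}.
#' @param path output path.
#' @param nodata sentinel written for NA cells.
#' @return \code{path}, invisibly.
#' @export
write_bathymetry <- function(grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid$nx), paste("nrows", grid$ny),
               paste("xllcorner", grid$x0), paste("yllcorner", grid$y0),
               paste("cellsize", grid$cellsize),
               paste("NODATA_value", nodata)), con)
  d <- grid$depth
  d[is.na(d)] <- nodata
  for (j in grid$ny:1)  # north row first
    writeLines(paste(format(d[, j], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Look up seabed depth at planar coordinates
#'
#' Nearest-cell (containing-cell) lookup; no interpolation. Points
#' outside the grid extent return NA.
#'
#' @param grid a \code{\link{bathy_grid}}.
#' @param x,y coordinate vectors, m.
#' @return numeric vector of seabed depths (m positive down); NA for
#'   out-of-grid points and NODATA cells.
#' @export
bathy_depth_at <- function(grid, x, y) {
  i <- floor((x - grid$x0) / grid$cellsize) + 1L
  j <- floor((y - grid$y0) / grid$cellsize) + 1L
  ok <- !is.na(i) & !is.na(j) & i >= 1L & i <= grid$nx & j >= 1L & j <= grid$ny
  out <- rep(NA_real_, length(x))
  out[ok] <- grid$depth[cbind(i[ok], j[ok])]
  out
}

#' Read an NDBC-style standard meteorological text file
#'
#' Whitespace-delimited hourly buoy records with a leading
#' \code{#}-prefixed header naming the columns (\code{YY/#YY, MM, DD,
#' hh} and optionally \code{mm}, plus \code{WDIR, WSPD, GST, WVHT,
#' PRES} among others). Sentinel values (99, 99.0, 999, 9999 and
#' variants) are mapped to NA. Records are floored to the containing
#' UTC hour and sorted.
#'
#' @param path path to the text file.
#' @return data frame of class \code{env_series} with columns \code{t}
#'   (POSIXct on whole UTC hours), \code{wave_height} (m),
#'   \code{wind_sustained} (m/s), \code{wind_gust} (m/s),
#'   \code{wind_dir} (deg from N) and \code{pressure} (mbar).
#' @export
read_environment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_i <- grep("^#", lines)
  if (length(hdr_i) == 0L) stop("no header line (starting with #) found")
  hdr <- strsplit(trimws(sub("^#", "", lines[hdr_i[1L]])), "\\s+")[[1L]]
  body <- lines[setdiff(seq_along(lines), hdr_i)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no parseable data rows in ", path)
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(r) {
    length(r) <- length(hdr)
    suppressWarnings(as.numeric(r))
  }))
  colnames(mat) <- toupper(hdr)
  get <- function(nm, sentinels) {
    if (!nm %in% colnames(mat)) return(rep(NA_real_, nrow(mat)))
    v <- mat[, nm]
    v[v %in% sentinels] <- NA
    v
  }
  yy <- mat[, intersect(c("YY", "YYYY"), colnames(mat))[1L]]
  yy <- ifelse(yy < 100, yy + ifelse(yy < 70, 2000, 1900), yy)
  t <- ISOdatetime(yy, mat[, "MM"], mat[, "DD"], mat[, "HH"], 0, 0,
                   tz = "UTC")
  keep <- !is.na(t)
  if (!any(keep)) stop("no parseable data rows in ", path)
  out <- data.frame(
    t = t[keep],
    wave_height = get("WVHT", c(99, 99.0, 99.00))[keep],
    wind_sustained = get("WSPD", c(99, 99.0))[keep],
    wind_gust = get("GST", c(99, 99.0))[keep],
    wind_dir = get("WDIR", c(999))[keep],
    pressure = get("PRES", c(9999, 9999.0))[keep])
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("env_series", "data.frame")
  out
}

#' Read the fate table
#'
#' One record per fish: the assigned ultimate fate and its time. Fates
#' are one of \code{predation, emigration, tag_loss, surface_mortality,
#' harvest, unknown, at_large}.
#'
#' @param path CSV with columns \code{fish_id,fate,fate_datetime_utc}.
#' @return data frame with \code{fish_id}, \code{fate},
#'   \code{fate_time} (POSIXct UTC).
#' @export
read_fates <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "fate", "fate_datetime_utc")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("fate file is missing column(s): ", paste(miss, collapse = ", "))
  ok <- c("predation", "emigration", "tag_loss", "surface_mortality",
          "harvest", "unknown", "at_large")
  if (!all(raw$fate %in% ok))
    stop("unknown fate value(s): ",
         paste(unique(setdiff(raw$fate, ok)), collapse = ", "))
  if (anyDuplicated(raw$fish_id)) stop("more than one fate record per fish")
  data.frame(fish_id = as.character(raw$fish_id), fate = raw$fate,
             fate_time = parse_utc(raw$fate_datetime_utc),
             stringsAsFactors = FALSE)
}

#' Write a fate table
#' @param fates data frame as from \code{\link{read_fates}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fates <- function(fates, path) {
  utils::write.csv(
    data.frame(fish_id = fates$fish_id, fate = fates$fate,
               fate_datetime_utc = format(fates$fate_time,
                                          "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
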