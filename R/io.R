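#' @importFrom stats median sd aggregate complete.cases cor setNames rnorm runif
#'   rbinom rgamma quantile
#' @importFrom utils read.csv write.csv head
NULL

# fixed vocabulary of road categories (UK open-roads classification)
ROAD_CATEGORIES <- c(
  "A Road", "B Road", "Local Access Road", "Local Road", "Minor Road",
  "Motorway", "Restricted Local Access Road", "Secondary Access Road"
)

# meteorological variable registry: short id -> descriptive name
MET_VARIABLES <- c(
  blh  = "boundary_layer_height",
  bld  = "boundary_layer_dissipation",
  tp   = "total_precipitation",
  mtpr = "mean_total_precipitation_rate",
  u10  = "u_wind_10m",
  v10  = "v_wind_10m",
  t2m  = "temperature_2m",
  d2m  = "dewpoint_2m",
  sp   = "surface_pressure",
  tcc  = "total_cloud_cover",
  fg10 = "wind_gust_10m",
  ssr  = "surface_net_solar_radiation"
)
MET_REQUIRED <- c("blh", "bld", "tp", "mtpr", "u10", "v10")
MET_POINTS <- c("C", "N", "NE", "E", "SE", "S", "SW", "W", "NW")

.met_short_name <- function(x) {
  out <- x
  long <- match(x, MET_VARIABLES)
  out[!is.na(long)] <- names(MET_VARIABLES)[long[!is.na(long)]]
  out
}

#' Monitor time series
#'
#' A `monitor_series` is a tibble with columns `time`, `pm1`, `pm25`, `pm10`
#' (concentrations, ug/m3), `temperature` (degC) and `relative_humidity` (%),
#' carrying the station identity and location as attributes. Timestamps must be
#' strictly increasing and equally spaced at a 1 h or 1 day step; negative
#' concentrations and out-of-range humidity are flagged missing.
#'
#' @param data data frame with the six measured columns and a `time` column
#'   (`POSIXct` for hourly data, `Date` for daily).
#' @param station_id station identifier (character scalar).
#' @param latitude,longitude WGS84 coordinates in decimal degrees.
#' @param step `"hour"` or `"day"`.
#' @return a validated `monitor_series` tibble.
#' @export
monitor_series <- function(data, station_id, latitude, longitude,
                           step = c("day", "hour")) {
  step <- match.arg(step)
  need <- c("time", "pm1", "pm25", "pm10", "temperature", "relative_humidity")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  data <- tibble::as_tibble(data[need])
  tnum <- as.numeric(data$time)
  if (is.unsorted(tnum, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  expected <- if (step == "hour") 3600 else if (inherits(data$time, "Date")) 1 else 86400
  if (nrow(data) > 1) {
    dt <- diff(tnum)
    if (any(abs(dt - expected) > 1e-6)) {
      stop("timestamps must be equally spaced at the declared step")
    }
  }
  for (col in c("pm1", "pm25", "pm10")) {
    bad <- !is.na(data[[col]]) & data[[col]] < 0
    if (any(bad)) {
      message(sum(bad), " negative ", col, " value(s) flagged missing")
      data[[col]][bad] <- NA_real_
    }
  }
  rh <- data$relative_humidity
  bad <- !is.na(rh) & (rh < 0 | rh > 100)
  if (any(bad)) {
    message(sum(bad), " out-of-range relative_humidity value(s) flagged missing")
    data$relative_humidity[bad] <- NA_real_
  }
  structure(data,
    class = c("monitor_series", class(data)),
    station_id = as.character(station_id),
    latitude = as.numeric(latitude), longitude = as.numeric(longitude),
    step = step
  )
}

#' @export
print.monitor_series <- function(x, ...) {
  cat(sprintf(
    "<monitor_series> station %s (%.5f, %.5f), %d %s steps\n",
    attr(x, "station_id"), attr(x, "latitude"), attr(x, "longitude"),
    nrow(x), attr(x, "step")
  ))
  NextMethod()
}

#' Read a monitor CSV
#'
#' Expects columns `time,pm1,pm25,pm10,temperature,relative_humidity` with
#' ISO-8601 timestamps, and a station table giving the station's coordinates.
#' Rows whose timestamp cannot be parsed are dropped with a message.
#'
#' @param source path to the CSV file.
#' @param station_meta data frame with columns `station_id`, `lat`, `lon`.
#' @param station_id the station the file belongs to; must appear in
#'   `station_meta`.
#' @param step `"day"` or `"hour"`.
#' @return a [monitor_series()].
#' @export
read_monitor_csv <- function(source, station_meta, station_id,
                             step = c("day", "hour")) {
  step <- match.arg(step)
  raw <- read.csv(source, stringsAsFactors = FALSE)
  need <- c("time", "pm1", "pm25", "pm10", "temperature", "relative_humidity")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  hit <- match(as.character(station_id), as.character(station_meta$station_id))
  if (is.na(hit)) stop("lookup error: unknown station_id '", station_id, "'")
  tm <- if (step == "day") {
    as.Date(raw$time)
  } else {
    as.POSIXct(raw$time, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  }
  bad <- is.na(tm)
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with unparseable timestamps")
    raw <- raw[!bad, , drop = FALSE]
    tm <- tm[!bad]
  }
  raw$time <- tm
  for (col in need[-1]) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  monitor_series(raw, station_id,
                 latitude = station_meta$lat[hit],
                 longitude = station_meta$lon[hit], step = step)
}

#' Write a monitor series back to CSV
#'
#' Values are written with 6 decimal places so a read/write round trip
#' reproduces them exactly at that precision.
#'
#' @param series a [monitor_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_monitor_csv <- function(series, path) {
  out <- as.data.frame(series)
  out$time <- if (attr(series, "step") == "day") {
    format(out$time, "%Y-%m-%d")
  } else {
    format(out$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) round(v, 6))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NaN")
  invisible(path)
}

#' Read a station table CSV (station_id, lat, lon)
#' @param source path to CSV.
#' @return tibble with character `station_id` and numeric `lat`, `lon`.
#' @export
read_station_table <- function(source) {
  st <- read.csv(source, stringsAsFactors = FALSE)
  miss <- setdiff(c("station_id", "lat", "lon"), names(st))
  if (length(miss) > 0) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  st$station_id <- as.character(st$station_id)
  tibble::as_tibble(st)
}

#' Resample an hourly monitor series to daily means
#'
#' Each day's value is the arithmetic mean of that day's non-missing hourly
#' values (UTC calendar days). A day with fewer than `coverage_min` of its 24
#' hours valid is flagged missing for that variable.
#'
#' @param series an hourly [monitor_series()].
#' @param coverage_min minimum fraction of valid hours required (default 0.75).
#' @return a daily `monitor_series`.
#' @export
resample_daily <- function(series, coverage_min = 0.75) {
  if (attr(series, "step") == "day") {
    warning("series is already daily; returning unchanged")
    return(series)
  }
  day <- as.Date(series$time, tz = "UTC")
  days <- sort(unique(day))
  vars <- c("pm1", "pm25", "pm10", "temperature", "relative_humidity")
  out <- tibble::tibble(time = days)
  for (col in vars) {
    v <- series[[col]]
    m <- tapply(v, day, function(z) mean(z, na.rm = TRUE))
    nvalid <- tapply(v, day, function(z) sum(!is.na(z)))
    m[nvalid < coverage_min * 24] <- NA_real_
    m[is.nan(m)] <- NA_real_
    out[[col]] <- as.numeric(m[as.character(days)])
  }
  monitor_series(out, attr(series, "station_id"),
                 attr(series, "latitude"), attr(series, "longitude"),
                 step = "day")
}

#' Meteorology table
#'
#' A `met_table` is a long tibble of daily meteorological values at the nine
#' named grid points around the study area: columns `date` (Date), `point`
#' (one of C, N, NE, E, SE, S, SW, W, NW), `variable` (short id, see
#' `met_variable_names()`), and `value`. All nine points must be present for
#' every date; boundary-layer height must be positive and precipitation
#' non-negative.
#'
#' @param data long data frame with the four columns.
#' @return a validated `met_table` tibble.
#' @export
met_table <- function(data) {
  miss <- setdiff(c("date", "point", "variable", "value"), names(data))
  if (length(miss) > 0) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  data <- tibble::as_tibble(data[c("date", "point", "variable", "value")])
  data$date <- as.Date(data$date)
  data$point <- as.character(data$point)
  data$variable <- .met_short_name(as.character(data$variable))
  bad_pt <- setdiff(unique(data$point), MET_POINTS)
  if (length(bad_pt) > 0) {
    stop("unknown met point label(s): ", paste(bad_pt, collapse = ", "))
  }
  tab <- table(unique(data[c("date", "point")])$date)
  if (any(tab != 9)) {
    stop("every date must carry all 9 met points")
  }
  blh <- data$value[data$variable == "blh"]
  if (any(!is.na(blh) & blh <= 0)) stop("boundary-layer height must be > 0")
  tp <- data$value[data$variable %in% c("tp", "mtpr")]
  if (any(!is.na(tp) & tp < 0)) stop("precipitation must be >= 0")
  structure(data, class = c("met_table", class(data)))
}

#' Names of the meteorological variables used by the feature set
#' @param long logical; return descriptive names instead of short ids.
#' @return character vector of 12 variable names.
#' @export
met_variable_names <- function(long = FALSE) {
  if (long) unname(MET_VARIABLES) else names(MET_VARIABLES)
}

#' Read daily meteorology
#'
#' Accepts either a long-format CSV or a CF-style netCDF file. Long CSVs may
#' already be in 9-point form (`date,point,variable,value`) or gridded
#' (`date,lat,lon,variable,value`); gridded sources are reduced to the grid
#' point nearest `centre` plus its 8 cardinal/ordinal neighbours at `spacing`
#' degrees. netCDF sources (dimensions time, latitude, longitude) require the
#' `ncdf4` package; hourly sources are averaged to days under the same coverage
#' rule as [resample_daily()].
#'
#' @param source path to CSV or netCDF file.
#' @param centre c(lon, lat) of the study-area centre (needed for gridded
#'   sources).
#' @param spacing neighbour spacing in degrees (default 0.25, one reanalysis
#'   grid step).
#' @param required short ids of variables that must be present.
#' @return a [met_table()].
#' @export
read_met <- function(source, centre = NULL, spacing = 0.25,
                     required = MET_REQUIRED) {
  is_nc <- grepl("\\.nc$", source, ignore.case = TRUE)
  df <- if (is_nc) .read_met_nc(source) else read.csv(source, stringsAsFactors = FALSE)
  if ("point" %in% names(df)) {
    long <- df
  } else if (all(c("lat", "lon") %in% names(df))) {
    if (is.null(centre)) stop("gridded met source requires `centre`")
    long <- .met_select_9(df, centre, spacing)
  } else {
    stop("format error: met source must have a `point` column or `lat`/`lon` columns")
  }
  long$variable <- .met_short_name(as.character(long$variable))
  have <- unique(long$variable)
  miss <- setdiff(required, have)
  if (length(miss) > 0) {
    stop("format error: missing met variable(s) ",
         paste(MET_VARIABLES[miss], collapse = ", "))
  }
  met_table(long)
}

.met_select_9 <- function(df, centre, spacing) {
  pts <- unique(df[c("lon", "lat")])
  if (nrow(pts) < 9) stop("extent error: fewer than 9 met grid points available")
  offsets <- list(
    C = c(0, 0), N = c(0, 1), NE = c(1, 1), E = c(1, 0), SE = c(1, -1),
    S = c(0, -1), SW = c(-1, -1), W = c(-1, 0), NW = c(-1, 1)
  )
  ci <- which.min((pts$lon - centre[1])^2 + (pts$lat - centre[2])^2)
  c_lon <- pts$lon[ci]; c_lat <- pts$lat[ci]
  out <- vector("list", 9)
  for (i in seq_along(offsets)) {
    lab <- names(offsets)[i]
    want_lon <- c_lon + offsets[[i]][1] * spacing
    want_lat <- c_lat + offsets[[i]][2] * spacing
    d2 <- (pts$lon - want_lon)^2 + (pts$lat - want_lat)^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > spacing / 2) {
      stop("extent error: no met grid point near ", lab, " neighbour position")
    }
    sub <- df[df$lon == pts$lon[j] & df$lat == pts$lat[j], , drop = FALSE]
    sub$point <- lab
    out[[i]] <- sub[c("date", "point", "variable", "value")]
  }
  do.call(rbind, out)
}

.read_met_nc <- function(source) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("reading netCDF requires the `ncdf4` package; ",
         "provide a long-format CSV instead")
  }
  nc <- ncdf4::nc_open(source)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "longitude"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "latitude"))
  tvar <- nc$dim$time
  dates <- as.Date(as.POSIXct(tvar$vals * 3600, origin = "1900-01-01", tz = "UTC"))
  rows <- list()
  for (vn in names(nc$var)) {
    arr <- ncdf4::ncvar_get(nc, vn) # lon x lat x time
    for (i in seq_along(lon)) for (j in seq_along(lat)) {
      rows[[length(rows) + 1]] <- data.frame(
        date = dates, lat = lat[j], lon = lon[i],
        variable = vn, value = as.numeric(arr[i, j, ])
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a met table to long-format CSV
#' @param met a [met_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(met, path) {
  out <- as.data.frame(met)
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Road layer
#'
#' A `road_layer` holds the polylines of one road category as a list of
#' two-column coordinate matrices, either geographic (`frame = "lonlat"`) or
#' local planar metres (`frame = "local"`). Every polyline must have at least
#' two vertices and the category must be one of the fixed 8-class vocabulary
#' (see [road_category_names()]).
#'
#' @param lines list of numeric matrices with >= 2 rows and 2 columns.
#' @param category road class, one of the 8-level vocabulary.
#' @param frame `"lonlat"` or `"local"`.
#' @return a `road_layer` object.
#' @export
road_layer <- function(lines, category, frame = c("local", "lonlat")) {
  frame <- match.arg(frame)
  if (!category %in% ROAD_CATEGORIES) {
    stop("unknown road category '", category, "'")
  }
  lines <- lapply(lines, function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2 || ncol(m) != 2) stop("each polyline needs >= 2 vertices")
    m
  })
  structure(list(lines = lines, category = category, frame = frame),
            class = "road_layer")
}

#' @export
print.road_layer <- function(x, ...) {
  cat(sprintf("<road_layer> %s: %d polylines, %d vertices (%s frame)\n",
              x$category, length(x$lines),
              sum(vapply(x$lines, nrow, integer(1))), x$frame))
  invisible(x)
}

#' The fixed 8-level road classification
#' @return character vector of the 8 category names.
#' @export
road_category_names <- function() ROAD_CATEGORIES

#' Read categorized road vectors from GeoJSON
#'
#' Parses LineString and MultiLineString features (EPSG:4326), groups them by
#' the road-class attribute and returns one [road_layer()] per category
#' present. MultiLineStrings are decomposed into their component polylines.
#' Features whose class does not map into the 8-level vocabulary are skipped
#' with a warning. If `anchor` is given, coordinates are reprojected into the
#' local planar frame.
#'
#' @param source path to a GeoJSON file.
#' @param class_field name of the feature property holding the road class.
#' @param class_map optional named character vector mapping source class values
#'   to the canonical category names; defaults to the identity on the canonical
#'   vocabulary.
#' @param anchor optional c(lon, lat); reproject into the local frame about it.
#' @return named list of `road_layer`, one per category present.
#' @export
read_roads <- function(source, class_field = "class", class_map = NULL,
                       anchor = NULL) {
  gj <- jsonlite::read_json(source, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  if (is.null(class_map)) class_map <- setNames(ROAD_CATEGORIES, ROAD_CATEGORIES)
  by_cat <- list()
  n_lines <- 0L
  skipped <- character(0)
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom) || !geom$type %in% c("LineString", "MultiLineString")) next
    n_lines <- n_lines + 1L
    cls <- as.character(f$properties[[class_field]])
    if (length(cls) == 0 || is.na(class_map[cls])) {
      skipped <- c(skipped, if (length(cls)) cls else "<missing>")
      next
    }
    cat_name <- unname(class_map[cls])
    parts <- if (geom$type == "LineString") list(geom$coordinates) else geom$coordinates
    for (p in parts) {
      m <- do.call(rbind, lapply(p, function(xy) c(xy[[1]], xy[[2]])))
      by_cat[[cat_name]] <- c(by_cat[[cat_name]], list(m))
    }
  }
  if (n_lines == 0L) stop("format error: no line features in ", source)
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " feature(s) with unmapped class: ",
            paste(unique(skipped), collapse = ", "))
  }
  out <- lapply(names(by_cat), function(cat_name) {
    lines <- by_cat[[cat_name]]
    if (!is.null(anchor)) {
      lines <- lapply(lines, function(m) lonlat_to_local(m[, 1], m[, 2], anchor))
      road_layer(lines, cat_name, frame = "local")
    } else {
      road_layer(lines, cat_name, frame = "lonlat")
    }
  })
  names(out) <- names(by_cat)
  out
}

#' Write road layers to GeoJSON
#' @param layers list of [road_layer()] in lonlat or local frame.
#' @param path output path.
#' @param anchor c(lon, lat) used to convert local-frame layers to geographic
#'   coordinates; required when any layer is in the local frame.
#' @param class_field property name for the category.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(layers, path, anchor = NULL,
                                class_field = "class") {
  feats <- list()
  for (ly in layers) {
    for (m in ly$lines) {
      if (ly$frame == "local") {
        if (is.null(anchor)) stop("local-frame layers need `anchor` to export")
        m <- local_to_lonlat(m[, 1], m[, 2], anchor)
      }
      coords <- lapply(seq_len(nrow(m)), function(i) list(m[i, 1], m[i, 2]))
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = setNames(list(ly$category), class_field),
        geometry = list(type = "LineString", coordinates = coords)
      )
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
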