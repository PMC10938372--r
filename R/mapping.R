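#' Cell centres of the prediction grid
#'
#' A regular rows x cols lattice of square cells of side `cell` metres, anchored
#' at its south-west corner, evaluated at cell centres in row-major order
#' (southernmost row first, west to east). The default 10 x 20 grid at 600 m
#' covers a 6 km x 12 km town with 200 points.
#'
#' @param anchor c(x, y) of the grid's south-west corner in the local frame
#'   (default the frame origin).
#' @param rows,cols lattice dimensions.
#' @param cell cell side (m).
#' @return tibble `point_id`, `row`, `col`, `x`, `y` with attributes `rows`,
#'   `cols`, `cell`, `anchor`.
#' @export
make_grid <- function(anchor = c(0, 0), rows = 10, cols = 20, cell = 600) {
  stopifnot(rows >= 1, cols >= 1, cell > 0)
  row_i <- rep(seq_len(rows), each = cols)
  col_i <- rep(seq_len(cols), times = rows)
  out <- tibble::tibble(
    point_id = paste0("r", row_i, "c", col_i),
    row = row_i, col = col_i,
    x = anchor[1] + (col_i - 0.5) * cell,
    y = anchor[2] + (row_i - 0.5) * cell
  )
  structure(out, class = c("map_grid", class(out)),
            rows = rows, cols = cols, cell = cell, anchor = anchor)
}

.grid_map <- function(grid, values, size_class, date = NULL, n_days = NULL) {
  out <- grid
  out$value <- values
  out$n_days <- if (is.null(n_days)) rep(1L, nrow(grid)) else n_days
  structure(out, class = c("grid_map", class(grid)),
            rows = attr(grid, "rows"), cols = attr(grid, "cols"),
            cell = attr(grid, "cell"), anchor = attr(grid, "anchor"),
            size_class = size_class, date = date)
}

#' Predict daily concentration maps
#'
#' Builds the feature vector of every (cell centre, date) from the full
#' training-monitor set and applies the trained network. Dates outside the
#' meteorology coverage are flagged (all-missing map) and the run continues.
#'
#' @param model a `trained_mlp`.
#' @param grid a [make_grid()] result.
#' @param dates Date vector to map.
#' @param monitors list of training [monitor_series()].
#' @param met a [met_table()].
#' @param raster a [rasterize_roads()] result.
#' @param config the [feature_config()] the model was trained under.
#' @return named list (by date) of `grid_map`s.
#' @export
predict_map <- function(model, grid, dates, monitors, met, raster,
                        config = feature_config()) {
  dates <- sort(unique(as.Date(dates)))
  covered <- dates %in% unique(met$date)
  if (!all(covered)) {
    warning(sum(!covered), " requested date(s) outside met coverage flagged missing")
  }
  maps <- setNames(vector("list", length(dates)), format(dates, "%Y-%m-%d"))
  for (i in which(!covered)) {
    maps[[i]] <- .grid_map(grid, rep(NA_real_, nrow(grid)),
                           model$size_class, date = dates[i],
                           n_days = rep(0L, nrow(grid)))
  }
  use <- dates[covered]
  if (length(use) > 0) {
    tab <- build_feature_table(grid, use, monitors, met, raster, config)
    pred <- predict(model, tab)
    key <- paste(tab$point_id, format(tab$date, "%Y-%m-%d"))
    for (d in use) {
      d <- as.Date(d, origin = "1970-01-01")
      lab <- format(d, "%Y-%m-%d")
      idx <- match(paste(grid$point_id, lab), key)
      vals <- ifelse(is.na(idx), NA_real_, pred[idx])
      maps[[lab]] <- .grid_map(grid, vals, model$size_class, date = d,
                               n_days = as.integer(!is.na(vals)))
    }
  }
  maps
}

#' Average daily maps into a period map
#'
#' Per-cell mean over the days with a valid value; the per-cell day count is
#' recorded. All maps must share geometry and size class.
#'
#' @param daily list of `grid_map`s from [predict_map()].
#' @return a period-average `grid_map`.
#' @export
average_map <- function(daily) {
  stopifnot(length(daily) >= 1)
  ref <- daily[[1]]
  for (m in daily[-1]) {
    if (!identical(m$point_id, ref$point_id) ||
        !identical(attr(m, "cell"), attr(ref, "cell")) ||
        !identical(attr(m, "size_class"), attr(ref, "size_class"))) {
      stop("contract error: maps differ in geometry or size class")
    }
  }
  vals <- vapply(daily, function(m) m$value, numeric(nrow(ref)))
  vals <- matrix(vals, nrow = nrow(ref))
  n <- rowSums(!is.na(vals))
  avg <- ifelse(n == 0, NA_real_, rowMeans(vals, na.rm = TRUE))
  .grid_map(ref[setdiff(names(ref), c("value", "n_days"))], avg,
            attr(ref, "size_class"), date = NULL, n_days = as.integer(n))
}

#' Export a grid map as CSV
#'
#' Canonical, bit-stable artifact: columns row, col, lon, lat, value, n_days in
#' row-major order. Negative predicted concentrations are floored at 0 on
#' export (physical display convention) with the count reported; the in-memory
#' map keeps the raw values.
#'
#' @param map a `grid_map`.
#' @param path output path.
#' @param anchor_lonlat c(lon, lat) of the local-frame origin, used to derive
#'   cell-centre geographic coordinates.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(map, path, anchor_lonlat) {
  ll <- local_to_lonlat(map$x, map$y, anchor_lonlat)
  v <- map$value
  n_neg <- sum(!is.na(v) & v < 0)
  if (n_neg > 0) message(n_neg, " negative cell value(s) floored at 0 on export")
  v <- pmax(v, 0)
  out <- data.frame(
    row = map$row, col = map$col,
    lon = round(ll[, "lon"], 8), lat = round(ll[, "lat"], 8),
    value = round(v, 6), n_days = map$n_days
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
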