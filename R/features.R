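#' Feature-set configuration
#'
#' Controls the blocks of the feature vector built for every (point, date).
#' Under the defaults the vector has exactly 151 named features: calendar (2) +
#' day-of-year sine/cosine (2) + easting/northing (2) + centre wind speed and
#' direction (2) + 12 meteorological variables at 9 grid points (108) +
#' per-size average PM over the available monitors (3) + a nearest-3-monitors
#' block of PM1/PM2.5/PM10, distance, bearing and wind concordance (18) +
#' per-size inverse-distance-weighted interpolation (3) + per-size
#' (average - IDW) difference (3) + road density per category (8).
#'
#' @param met_vars short ids of the meteorological variables (12 by default).
#' @param k number of nearest monitors (default 3).
#' @param idw_power IDW exponent (default 2).
#' @param idw_eps distance floor in metres for IDW weights (default 1).
#' @param raster_res road raster resolution in metres (default 4; 50 available
#'   for the coarser convention).
#' @param window road-density window side in metres (default 200).
#' @param blocks named logical vector switching feature blocks on/off.
#' @return a `feature_config` list.
#' @export
feature_config <- function(met_vars = met_variable_names(),
                           k = 3, idw_power = 2, idw_eps = 1,
                           raster_res = 4, window = 200,
                           blocks = c(calendar = TRUE, doy = TRUE,
                                      position = TRUE, wind = TRUE,
                                      met = TRUE, network = TRUE,
                                      roads = TRUE)) {
  stopifnot(k >= 1, idw_power > 0, idw_eps > 0, raster_res > 0, window > 0)
  cfg <- list(met_vars = met_vars, k = k, idw_power = idw_power,
              idw_eps = idw_eps, raster_res = raster_res, window = window,
              blocks = blocks)
  class(cfg) <- "feature_config"
  cfg
}

.road_feature_name <- function(cat_name) {
  paste0("road_", gsub(" +", "_", tolower(cat_name)))
}

#' Ordered feature names for a configuration
#' @param config a [feature_config()].
#' @return character vector (length 151 under defaults).
#' @export
feature_names <- function(config = feature_config()) {
  b <- config$blocks
  sizes <- c("pm1", "pm25", "pm10")
  nm <- character(0)
  if (b[["calendar"]]) nm <- c(nm, "dow", "month")
  if (b[["doy"]]) nm <- c(nm, "doy_sin", "doy_cos")
  if (b[["position"]]) nm <- c(nm, "easting", "northing")
  if (b[["wind"]]) nm <- c(nm, "wind_speed_c", "wind_dir_c")
  if (b[["met"]]) {
    nm <- c(nm, as.vector(vapply(
      config$met_vars, function(v) paste0(v, "_", MET_POINTS),
      character(length(MET_POINTS))
    )))
  }
  if (b[["network"]]) {
    nm <- c(nm, paste0("avg_", sizes))
    for (r in seq_len(config$k)) {
      nm <- c(nm, paste0("nb", r, "_", c(sizes, "dist", "bearing", "upwind")))
    }
    nm <- c(nm, paste0("idw_", sizes), paste0("avgdiff_", sizes))
  }
  if (b[["roads"]]) nm <- c(nm, .road_feature_name(road_category_names()))
  nm
}

#' Rasterize road layers to per-category vertex-count grids
#'
#' Each category's polyline vertices are binned into square cells of side
#' `resolution`; the raster is stored sparsely as (cell index, count) so the
#' total count always equals the number of vertices rasterized.
#'
#' @param layers list of local-frame [road_layer()].
#' @param resolution cell side in metres (default 4).
#' @return a `road_raster`: named list (all 8 categories, absent ones empty) of
#'   data frames `ix, iy, n`, with attribute `resolution`.
#' @export
rasterize_roads <- function(layers, resolution = 4) {
  out <- setNames(vector("list", length(road_category_names())),
                  road_category_names())
  for (cat_name in road_category_names()) {
    ly <- NULL
    for (l in layers) if (l$category == cat_name) ly <- l
    if (is.null(ly)) {
      out[[cat_name]] <- data.frame(ix = integer(0), iy = integer(0),
                                    n = integer(0))
      next
    }
    if (ly$frame != "local") stop("rasterize_roads needs local-frame layers")
    verts <- do.call(rbind, ly$lines)
    ix <- floor(verts[, 1] / resolution)
    iy <- floor(verts[, 2] / resolution)
    key <- paste(ix, iy)
    tab <- table(key)
    first <- !duplicated(key)
    out[[cat_name]] <- data.frame(
      ix = ix[first], iy = iy[first],
      n = as.integer(tab[key[first]])
    )
  }
  structure(out, class = "road_raster", resolution = resolution)
}

#' Road density around points
#'
#' For each point and category, sums the raster counts of all cells whose
#' extent intersects the square window of side `window` centred on the point
#' (the local road-density index).
#'
#' @param raster a [rasterize_roads()] result.
#' @param points two-column matrix of local x, y (m).
#' @param window window side in metres (default 200).
#' @return numeric matrix, points x 8 categories.
#' @export
road_density <- function(raster, points, window = 200) {
  points <- matrix(as.numeric(points), ncol = 2)
  res <- attr(raster, "resolution")
  half <- window / 2
  cats <- names(raster)
  out <- matrix(0, nrow(points), length(cats),
                dimnames = list(NULL, .road_feature_name(cats)))
  for (ci in seq_along(cats)) {
    cells <- raster[[ci]]
    if (nrow(cells) == 0) next
    cx0 <- cells$ix * res; cx1 <- cx0 + res
    cy0 <- cells$iy * res; cy1 <- cy0 + res
    for (pi in seq_len(nrow(points))) {
      hit <- cx0 <= points[pi, 1] + half & cx1 >= points[pi, 1] - half &
        cy0 <= points[pi, 2] + half & cy1 >= points[pi, 2] - half
      out[pi, ci] <- sum(cells$n[hit])
    }
  }
  out
}

#' Wind concordance indicator
#'
#' Returns 1 when the monitor lies upwind of the point (its air can advect
#' towards the point), 0 when downwind. The monitor is upwind when the angular
#' difference between the bearing from the point to the monitor and the
#' meteorological wind-from direction is at most 90 degrees; calm wind (speed
#' 0) returns 0 by convention.
#'
#' @param bearing_to_monitor degrees clockwise from north; vectorised.
#' @param u,v wind components (m/s); scalars or vectors.
#' @return integer 0/1 vector.
#' @export
wind_concordance <- function(bearing_to_monitor, u, v) {
  n <- max(length(bearing_to_monitor), length(u), length(v))
  b <- rep_len(bearing_to_monitor, n)
  u <- rep_len(u, n); v <- rep_len(v, n)
  out <- integer(n)
  calm <- sqrt(u^2 + v^2) == 0
  wfrom <- (atan2(-u, -v) * 180 / pi) %% 360
  diff <- abs(((wfrom - b + 180) %% 360) - 180)
  out[!calm] <- as.integer(diff[!calm] <= 90)
  out
}

#' Nearest monitors to a point
#'
#' Orders candidate stations by ascending distance, breaking ties by ascending
#' station id, and returns the first `k` after removing `exclude`.
#'
#' @param point c(x, y) in the local frame.
#' @param candidates tibble with `station_id`, `x`, `y` or a list of
#'   [monitor_series()] carrying `x`/`y` attributes.
#' @param k how many stations (default 3).
#' @param exclude station ids to remove before ranking.
#' @return tibble `station_id`, `distance` (m), `bearing` (deg), k rows.
#' @export
nearest_monitors <- function(point, candidates, k = 3, exclude = character(0)) {
  if (!is.data.frame(candidates)) {
    candidates <- tibble::tibble(
      station_id = vapply(candidates, attr, character(1), "station_id"),
      x = vapply(candidates, attr, numeric(1), "x"),
      y = vapply(candidates, attr, numeric(1), "y")
    )
  }
  cand <- candidates[!candidates$station_id %in% exclude, , drop = FALSE]
  if (nrow(cand) < k) {
    stop("configuration error: only ", nrow(cand),
         " candidate monitors for k = ", k)
  }
  dx <- cand$x - point[1]; dy <- cand$y - point[2]
  d <- sqrt(dx^2 + dy^2)
  b <- ifelse(d == 0, 0, (atan2(dx, dy) * 180 / pi) %% 360)
  ord <- order(d, cand$station_id)
  sel <- ord[seq_len(k)]
  tibble::tibble(station_id = cand$station_id[sel], distance = d[sel],
                 bearing = b[sel])
}

#' Inverse-distance-weighted interpolation
#'
#' `sum(w * v) / sum(w)` with `w = 1 / max(d, eps)^power`. If any distance is
#' below `eps` the point is treated as an exact hit and that value is returned.
#'
#' @param values numeric vector.
#' @param distances matching distances in metres (>= 0).
#' @param power IDW exponent (default 2).
#' @param eps distance floor in metres (default 1).
#' @return interpolated scalar.
#' @export
idw <- function(values, distances, power = 2, eps = 1) {
  if (length(values) == 0) stop("value error: empty input to idw")
  stopifnot(length(values) == length(distances), all(distances >= 0, na.rm = TRUE))
  hit <- which(distances < eps)
  if (length(hit) > 0) return(values[hit[1]])
  w <- 1 / pmax(distances, eps)^power
  sum(w * values) / sum(w)
}

# ---- feature-table engine ----------------------------------------------------

# wide days x (12 vars x 9 points) matrix from a long met table
.met_wide <- function(met, dates, met_vars) {
  cols <- as.vector(vapply(met_vars, function(v) paste0(v, "_", MET_POINTS),
                           character(length(MET_POINTS))))
  m <- matrix(NA_real_, length(dates), length(cols),
              dimnames = list(NULL, cols))
  key <- paste0(met$variable, "_", met$point)
  di <- match(met$date, dates)
  keep <- !is.na(di) & key %in% cols
  m[cbind(di[keep], match(key[keep], cols))] <- met$value[keep]
  if (anyNA(m)) stop("coverage error: met data does not cover all dates/variables")
  m
}

# station x size PM matrices per date with station-median imputation
.monitor_arrays <- function(monitors, dates, impute = TRUE) {
  sizes <- c("pm1", "pm25", "pm10")
  ids <- vapply(monitors, attr, character(1), "station_id")
  arr <- array(NA_real_, c(length(dates), length(ids), 3),
               dimnames = list(NULL, ids, sizes))
  med <- matrix(NA_real_, length(ids), 3, dimnames = list(ids, sizes))
  for (j in seq_along(ids)) {
    ms <- monitors[[j]]
    di <- match(as.Date(ms$time), dates)
    for (s in seq_along(sizes)) {
      v <- ms[[sizes[s]]]
      keep <- !is.na(di)
      arr[di[keep], j, s] <- v[keep]
      med[j, s] <- median(v, na.rm = TRUE)
    }
  }
  n_imp <- sum(is.na(arr))
  if (impute && n_imp > 0) {
    for (j in seq_along(ids)) for (s in 1:3) {
      miss <- is.na(arr[, j, s])
      arr[miss, j, s] <- med[j, s]
    }
    message("imputed ", n_imp, " missing monitor value(s) by station median")
  }
  list(arr = arr, med = med, ids = ids)
}

#' Build the feature table for a set of points and dates
#'
#' The engine behind [build_feature_vector()], [build_tables()] and
#' [predict_map()]: assembles the configured feature blocks for every
#' (point, date) pair, using only the monitor series passed in `monitors` (the
#' leakage guard is the caller choosing that set). Missing monitor values are
#' imputed by the station's median over its provided record; a row is dropped
#' (with a message) only when all of its nearest monitors have no record at
#' all.
#'
#' @param points tibble with `point_id`, `x`, `y` (local metres).
#' @param dates Date vector.
#' @param monitors list of daily [monitor_series()] with `x`/`y` attributes —
#'   the stations whose concentrations may enter the features.
#' @param met a [met_table()] covering `dates`.
#' @param raster a [rasterize_roads()] result.
#' @param config a [feature_config()].
#' @param exclude_self named character vector mapping `point_id` to a station
#'   id that must not contribute to that point's network features (the
#'   training-table rule).
#' @param targets optional named list of [monitor_series()] keyed by
#'   `point_id` supplying the target PM columns.
#' @return a `feature_table` tibble: `point_id`, `date`, the feature columns
#'   (attribute `feature_names`), and `pm1`, `pm25`, `pm10` target columns
#'   (NA for non-monitor points).
#' @export
build_feature_table <- function(points, dates, monitors, met, raster,
                                config = feature_config(),
                                exclude_self = NULL, targets = NULL) {
  sizes <- c("pm1", "pm25", "pm10")
  fnames <- feature_names(config)
  np <- nrow(points)
  dates <- sort(unique(as.Date(dates)))
  nd <- length(dates)
  b <- config$blocks

  mon <- .monitor_arrays(monitors, dates)
  metw <- if (b[["met"]] || b[["wind"]]) .met_wide(met, dates, config$met_vars)
  u_c <- .met_centre(met, "u10", dates)
  v_c <- .met_centre(met, "v10", dates)

  # static, per-point geometry: neighbours, distances, bearings, roads
  k <- config$k
  nb_idx <- matrix(NA_integer_, np, k)
  nb_dist <- matrix(NA_real_, np, k)
  nb_bear <- matrix(NA_real_, np, k)
  allow <- matrix(TRUE, np, length(mon$ids)) # stations allowed per point
  for (i in seq_len(np)) {
    excl <- character(0)
    if (!is.null(exclude_self) && points$point_id[i] %in% names(exclude_self)) {
      excl <- exclude_self[[points$point_id[i]]]
      allow[i, mon$ids %in% excl] <- FALSE
    }
    nb <- nearest_monitors(c(points$x[i], points$y[i]), monitors,
                           k = k, exclude = excl)
    nb_idx[i, ] <- match(nb$station_id, mon$ids)
    nb_dist[i, ] <- nb$distance
    nb_bear[i, ] <- nb$bearing
  }
  roads <- if (b[["roads"]]) {
    road_density(raster, cbind(points$x, points$y), window = config$window)
  }

  dow <- as.integer(format(dates, "%u")) - 1L
  mth <- as.integer(format(dates, "%m"))
  doy <- as.integer(format(dates, "%j"))

  big <- matrix(NA_real_, np * nd, length(fnames),
                dimnames = list(NULL, fnames))
  tgt <- matrix(NA_real_, np * nd, 3, dimnames = list(NULL, sizes))
  if (!is.null(targets)) {
    tgt_arr <- .monitor_arrays(targets, dates, impute = FALSE)
  }
  w_allow <- allow / rowSums(allow) # per-point averaging weights

  for (d in seq_len(nd)) {
    rows <- (d - 1) * np + seq_len(np)
    if (b[["calendar"]]) {
      big[rows, "dow"] <- dow[d]
      big[rows, "month"] <- mth[d]
    }
    if (b[["doy"]]) {
      big[rows, "doy_sin"] <- sin(2 * pi * doy[d] / 365.25)
      big[rows, "doy_cos"] <- cos(2 * pi * doy[d] / 365.25)
    }
    if (b[["position"]]) {
      big[rows, "easting"] <- points$x
      big[rows, "northing"] <- points$y
    }
    if (b[["wind"]]) {
      spd <- sqrt(u_c[d]^2 + v_c[d]^2)
      big[rows, "wind_speed_c"] <- spd
      big[rows, "wind_dir_c"] <- if (spd == 0) 0 else
        (atan2(-u_c[d], -v_c[d]) * 180 / pi) %% 360
    }
    if (b[["met"]]) {
      big[rows, colnames(metw)] <- matrix(metw[d, ], np, ncol(metw),
                                          byrow = TRUE)
    }
    if (b[["network"]]) {
      pm_d <- mon$arr[d, , , drop = TRUE] # stations x sizes
      if (is.null(dim(pm_d))) pm_d <- matrix(pm_d, ncol = 3,
                                             dimnames = list(NULL, sizes))
      avg <- w_allow %*% pm_d # points x sizes
      big[rows, paste0("avg_", sizes)] <- avg
      for (r in seq_len(k)) {
        vi <- nb_idx[, r]
        big[rows, paste0("nb", r, "_", sizes)] <- pm_d[vi, , drop = FALSE]
        big[rows, paste0("nb", r, "_dist")] <- nb_dist[, r]
        big[rows, paste0("nb", r, "_bearing")] <- nb_bear[, r]
        big[rows, paste0("nb", r, "_upwind")] <-
          wind_concordance(nb_bear[, r], u_c[d], v_c[d])
      }
      w <- 1 / pmax(nb_dist, config$idw_eps)^config$idw_power
      for (s in seq_len(3)) {
        vals <- matrix(pm_d[nb_idx, s], np, k)
        iv <- rowSums(w * vals) / rowSums(w)
        hit <- nb_dist < config$idw_eps
        if (any(hit)) {
          first_hit <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA)
          has <- !is.na(first_hit)
          iv[has] <- vals[cbind(which(has), first_hit[has])]
        }
        big[rows, paste0("idw_", sizes[s])] <- iv
        big[rows, paste0("avgdiff_", sizes[s])] <- avg[, s] - iv
      }
    }
    if (b[["roads"]]) big[rows, colnames(roads)] <- roads
    if (!is.null(targets)) {
      ti <- match(points$point_id, tgt_arr$ids)
      has <- !is.na(ti)
      tgt[rows[has], ] <- tgt_arr$arr[d, ti[has], , drop = FALSE]
    }
  }

  out <- tibble::tibble(
    point_id = rep(points$point_id, nd),
    date = rep(dates, each = np)
  )
  out <- cbind(out, tibble::as_tibble(big), tibble::as_tibble(tgt))
  out <- tibble::as_tibble(out)
  bad <- !stats::complete.cases(out[, fnames])
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with unconstructible features")
    out <- out[!bad, , drop = FALSE]
  }
  structure(out, class = c("feature_table", class(out)),
            feature_names = fnames, config = config)
}

#' Build the feature vector for one point and day
#'
#' @param point c(x, y) local metres.
#' @param date a Date.
#' @param monitors,met,raster,config as in [build_feature_table()].
#' @return named numeric vector (length 151 under the default configuration).
#' @export
build_feature_vector <- function(point, date, monitors, met, raster,
                                 config = feature_config()) {
  tab <- build_feature_table(
    tibble::tibble(point_id = "p", x = point[1], y = point[2]),
    as.Date(date), monitors, met, raster, config
  )
  if (nrow(tab) == 0) stop("feature construction failed for the requested row")
  unlist(tab[1, attr(tab, "feature_names")])
}

#' Build leakage-separated train and evaluation feature tables
#'
#' Training rows exclude the target station from its own neighbour set and from
#' the average-PM features; evaluation rows see only the training monitors, so
#' the evaluation table is invariant to any perturbation of the evaluation
#' stations' concentrations.
#'
#' @param monitors named list of daily [monitor_series()] with `x`/`y`
#'   attributes (names = station ids).
#' @param met a [met_table()].
#' @param raster a [rasterize_roads()] result.
#' @param split list with character vectors `train` and `eval` (disjoint;
#'   >= 4 training stations).
#' @param config a [feature_config()].
#' @param dates optional Date vector; defaults to the union of monitor dates.
#' @return list of two `feature_table`s: `train` and `eval`.
#' @export
build_tables <- function(monitors, met, raster, split,
                         config = feature_config(), dates = NULL) {
  ids <- vapply(monitors, attr, character(1), "station_id")
  names(monitors) <- ids
  if (length(intersect(split$train, split$eval)) > 0) {
    stop("configuration error: train/eval station sets overlap")
  }
  if (length(split$train) < 4) {
    stop("configuration error: need >= 4 training stations")
  }
  missing_ids <- setdiff(c(split$train, split$eval), ids)
  if (length(missing_ids) > 0) {
    stop("unknown station id(s): ", paste(missing_ids, collapse = ", "))
  }
  if (is.null(dates)) {
    dates <- sort(unique(do.call(c, lapply(monitors[split$train],
                                           function(m) as.Date(m$time)))))
  }
  pts <- function(ids) tibble::tibble(
    point_id = ids,
    x = vapply(monitors[ids], attr, numeric(1), "x"),
    y = vapply(monitors[ids], attr, numeric(1), "y")
  )
  train_mon <- monitors[split$train]
  train_tab <- build_feature_table(
    pts(split$train), dates, train_mon, met, raster, config,
    exclude_self = setNames(split$train, split$train),
    targets = train_mon
  )
  eval_tab <- build_feature_table(
    pts(split$eval), dates, train_mon, met, raster, config,
    targets = monitors[split$eval]
  )
  list(train = train_tab, eval = eval_tab)
}
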