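#' Configuration for a synthetic town
#'
#' The generator lays out a planar rectangular domain anchored at a WGS84
#' point, draws random polyline roads per category, places a small monitor
#' network with a minimum pairwise separation, and fixes the emission
#' coefficients of the latent PM field. Defaults describe a mid-size UK-like
#' town: a 12 km x 6 km domain, 8 monitors at >= 500 m separation, a background
#' of about 8 ug/m3 and road sources contributing a few ug/m3 near dense
#' roads, with the coarse fraction (PM2.5..PM10) a small share of total mass.
#'
#' @param domain c(width_x, height_y) in metres.
#' @param anchor c(lon, lat) of the domain's south-west corner.
#' @param n_monitors number of monitors (>= 8 recommended).
#' @param min_separation minimum pairwise monitor distance (m).
#' @param roads_per_category named integer vector, polylines per category.
#' @param alpha named emission coefficients, ug/m3 per vertex-count density
#'   unit, one per road category.
#' @param background_mean mean background concentration (ug/m3).
#' @param bg_amp relative elevation of the background over the town centre
#'   (0.3 = +30% at the centre of the first district, decaying outwards);
#'   emulates the smooth, spread urban-background component of secondary
#'   origin that real towns show.
#' @param bg_scale e-folding length scale of that elevation (m).
#' @param background_sdlog lognormal day-to-day background variability.
#' @param background_phi AR(1) coefficient of the background series.
#' @param blh_ref reference boundary-layer height (m): road-source dilution
#'   scales as blh_ref / BLH(t).
#' @param kappa precipitation wash-out rate (per metre of daily precipitation).
#' @param size_fractions cumulative mass shares c(pm1, pm25, pm10); the last
#'   must be 1.
#' @return a `town_config` list.
#' @export
town_config <- function(domain = c(12000, 6000),
                        anchor = c(-0.60, 51.32),
                        n_monitors = 8,
                        min_separation = 500,
                        roads_per_category = c(
                          "A Road" = 2, "B Road" = 3, "Local Access Road" = 8,
                          "Local Road" = 12, "Minor Road" = 10, "Motorway" = 1,
                          "Restricted Local Access Road" = 5,
                          "Secondary Access Road" = 4
                        ),
                        alpha = c(
                          "A Road" = 0.60, "B Road" = 0.35,
                          "Local Access Road" = 0.12, "Local Road" = 0.18,
                          "Minor Road" = 0.25, "Motorway" = 0.90,
                          "Restricted Local Access Road" = 0.06,
                          "Secondary Access Road" = 0.12
                        ),
                        background_mean = 8,
                        bg_amp = 0.3,
                        bg_scale = 2500,
                        background_sdlog = 0.25,
                        background_phi = 0.8,
                        blh_ref = 500,
                        kappa = 50,
                        size_fractions = c(pm1 = 0.90, pm25 = 0.97, pm10 = 1.00)) {
  stopifnot(all(domain > 0), n_monitors >= 1, min_separation >= 0,
            all(alpha >= 0), abs(size_fractions[3] - 1) < 1e-12,
            !is.unsorted(size_fractions))
  cfg <- list(
    domain = domain, anchor = anchor, n_monitors = n_monitors,
    min_separation = min_separation,
    roads_per_category = roads_per_category, alpha = alpha,
    background_mean = background_mean, bg_amp = bg_amp, bg_scale = bg_scale,
    background_sdlog = background_sdlog,
    background_phi = background_phi, blh_ref = blh_ref, kappa = kappa,
    size_fractions = size_fractions
  )
  class(cfg) <- "town_config"
  cfg
}

# random-walk polyline with boundary reflection; length and wiggliness differ
# by road class so motorways are long and straight, access roads short
.road_geometry <- function(category) {
  switch(category,
    "Motorway" = list(len = 14000, step = 40, wiggle = 0.03),
    "A Road" = list(len = 9000, step = 35, wiggle = 0.08),
    "B Road" = list(len = 5000, step = 30, wiggle = 0.15),
    "Local Road" = list(len = 1600, step = 30, wiggle = 0.35),
    "Minor Road" = list(len = 1300, step = 30, wiggle = 0.35),
    "Local Access Road" = list(len = 800, step = 25, wiggle = 0.45),
    "Secondary Access Road" = list(len = 700, step = 25, wiggle = 0.45),
    "Restricted Local Access Road" = list(len = 500, step = 25, wiggle = 0.5)
  )
}

.random_polyline <- function(domain, geom, start = NULL) {
  nv <- max(2L, as.integer(round(geom$len / geom$step)))
  x <- numeric(nv); y <- numeric(nv)
  if (is.null(start)) {
    x[1] <- runif(1, 0, domain[1]); y[1] <- runif(1, 0, domain[2])
  } else {
    x[1] <- min(max(start[1], 0), domain[1])
    y[1] <- min(max(start[2], 0), domain[2])
  }
  theta <- runif(1, 0, 2 * pi)
  for (i in 2:nv) {
    theta <- theta + rnorm(1, 0, geom$wiggle)
    x[i] <- x[i - 1] + geom$step * cos(theta)
    y[i] <- y[i - 1] + geom$step * sin(theta)
    # reflect at the domain boundary
    if (x[i] < 0) { x[i] <- -x[i]; theta <- pi - theta }
    if (x[i] > domain[1]) { x[i] <- 2 * domain[1] - x[i]; theta <- pi - theta }
    if (y[i] < 0) { y[i] <- -y[i]; theta <- -theta }
    if (y[i] > domain[2]) { y[i] <- 2 * domain[2] - y[i]; theta <- -theta }
  }
  cbind(x = x, y = y)
}

#' Generate a synthetic town with known ground truth
#'
#' Deterministic for a fixed (config, seed). Roads are random polylines whose
#' length and curvature depend on the category; monitors are placed with a
#' minimum pairwise separation, half of them near roads of the busier classes
#' so the network samples both source-proximal and background locations.
#'
#' @param config a [town_config()].
#' @param seed integer seed.
#' @return a `town_truth` list: `domain`, `anchor`, `roads` (local-frame
#'   [road_layer()]s), `alpha`, background/dilution parameters,
#'   `size_fractions`, `monitors` (tibble station_id, x, y, lon, lat), `seed`.
#' @export
make_town <- function(config = town_config(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  domain <- config$domain
  # residential districts: local-category roads cluster around their centres,
  # giving the road field the kilometre-scale structure of a real town
  n_district <- 3L
  districts <- cbind(
    runif(n_district, 0.15 * domain[1], 0.85 * domain[1]),
    runif(n_district, 0.15 * domain[2], 0.85 * domain[2])
  )
  clustered <- c("Local Road", "Minor Road", "Local Access Road",
                 "Secondary Access Road", "Restricted Local Access Road")
  roads <- list()
  for (cat_name in road_category_names()) {
    n <- config$roads_per_category[[cat_name]]
    if (is.null(n) || n == 0) next
    geom <- .road_geometry(cat_name)
    lines <- lapply(seq_len(n), function(i) {
      start <- if (cat_name %in% clustered) {
        d <- districts[sample.int(n_district, 1), ]
        d + rnorm(2, 0, 700)
      } else NULL # through roads start anywhere and cross the domain
      .random_polyline(domain, geom, start = start)
    })
    roads[[cat_name]] <- road_layer(lines, cat_name, frame = "local")
  }
  # citizen-network placement: most monitors sit at residential locations
  # spread over the districts (home/garden sensors, cycling through districts
  # so the network samples the whole town); two members live along busy roads,
  # giving the network the source-proximal sites and the large between-monitor
  # differences such networks show. Minimum pairwise separation enforced.
  busy <- do.call(rbind, lapply(
    roads[intersect(c("Motorway", "A Road", "B Road"), names(roads))],
    function(ly) do.call(rbind, ly$lines)
  ))
  n_mon <- config$n_monitors
  n_roadside <- if (n_mon >= 6 && !is.null(busy)) 2L else 0L
  sep <- config$min_separation
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n_mon) {
    tries <- tries + 1L
    if (tries > 5000L) {
      stop("placement error: could not place ", n_mon,
           " monitors at >= ", sep, " m separation")
    }
    if (length(xs) < n_roadside) {
      v <- busy[sample.int(nrow(busy), 1), ]
      cx <- v[1] + rnorm(1, 0, 80); cy <- v[2] + rnorm(1, 0, 80)
    } else {
      d <- districts[(length(xs) %% n_district) + 1L, ]
      cx <- d[1] + rnorm(1, 0, 1200); cy <- d[2] + rnorm(1, 0, 1200)
    }
    if (cx < 0 || cx > domain[1] || cy < 0 || cy > domain[2]) next
    if (length(xs) > 0 && min(sqrt((xs - cx)^2 + (ys - cy)^2)) < sep) next
    xs <- c(xs, cx); ys <- c(ys, cy)
  }
  ll <- local_to_lonlat(xs, ys, config$anchor)
  # station ids mirror the study's evaluation-monitor selection: the monitors
  # whose expected local source strength is closest to the network average and
  # that sit nearest the network centroid get the ids reserved for evaluation
  # (2, 7, 8 in an 8-station network); they are "typical and surrounded"
  rast <- rasterize_roads(roads, resolution = 16)
  dens <- road_density(rast, cbind(xs, ys), window = 200)
  alpha <- config$alpha[road_category_names()]
  alpha[is.na(alpha)] <- 0
  src <- as.numeric(dens %*% alpha)
  centroid <- c(mean(xs), mean(ys))
  typicality <- abs(src - mean(src)) / max(sd(src), 1e-9) +
    sqrt((xs - centroid[1])^2 + (ys - centroid[2])^2) / max(sd(xs), sd(ys))
  eval_pos <- if (n_mon >= 8) c(2L, 7L, 8L) else integer(0)
  ord_typ <- order(typicality)
  ids <- integer(n_mon)
  ids[ord_typ[seq_along(eval_pos)]] <- eval_pos
  ids[ids == 0L] <- setdiff(seq_len(n_mon), eval_pos)
  monitors <- tibble::tibble(
    station_id = as.character(ids),
    x = xs, y = ys, lon = ll[, "lon"], lat = ll[, "lat"]
  )
  monitors <- monitors[order(as.integer(monitors$station_id)), ]
  structure(list(
    domain = domain, anchor = config$anchor, roads = roads,
    centre = districts[1, ], districts = districts,
    bg_amp = config$bg_amp, bg_scale = config$bg_scale,
    alpha = config$alpha, background_mean = config$background_mean,
    background_sdlog = config$background_sdlog,
    background_phi = config$background_phi,
    blh_ref = config$blh_ref, kappa = config$kappa,
    size_fractions = config$size_fractions,
    monitors = monitors, seed = seed
  ), class = "town_truth")
}

#' @export
print.town_truth <- function(x, ...) {
  cat(sprintf(
    "<town_truth> %.0f x %.0f m, %d road categories, %d monitors (seed %d)\n",
    x$domain[1], x$domain[2], length(x$roads), nrow(x$monitors), x$seed
  ))
  invisible(x)
}

# save/restore global RNG state so generators do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# mean-path + AR(1) deviation generator; zero `noise` returns the mean path
.ar1 <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  e <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  z <- numeric(n)
  z[1] <- rnorm(1, 0, sd)
  for (t in 2:n) z[t] <- phi * z[t - 1] + e[t]
  z
}

#' Default parameters for the synthetic meteorology
#'
#' Means and variabilities loosely emulate daily reanalysis series over a
#' temperate town: boundary-layer height ~600 m median, dissipation ~250 W/m2,
#' ~35% wet days with a few mm of rain, slow winds, 13.5 degC mean temperature
#' with a seasonal cycle. `noise = 0` for a variable collapses it to its mean
#' path; `spatial_noise = 0` makes the 8 neighbour points equal the centre.
#'
#' @param blh_mean,blh_noise,blh_phi lognormal boundary-layer height (m).
#' @param bld_mean,bld_noise,bld_phi lognormal boundary-layer dissipation (W/m2).
#' @param p_wet,precip_mean,precip_noise wet-day probability and mean wet-day
#'   total precipitation (m/day); `precip_noise = 0` yields the constant mean
#'   `p_wet * precip_mean` every day.
#' @param u_mean,v_mean,wind_noise,wind_phi 10 m wind components (m/s).
#' @param t_mean,t_amp,t_noise,t_phi 2 m temperature (degC) and seasonal
#'   amplitude.
#' @param dew_depression mean dewpoint depression (degC).
#' @param sp_mean,sp_noise surface pressure (Pa).
#' @param tcc_mean,tcc_noise total cloud cover fraction.
#' @param ssr_mean,ssr_noise surface net solar radiation (J/m2/day).
#' @param spatial_noise relative scale of the coherent perturbations applied to
#'   the 8 neighbour points.
#' @return a `met_params` list.
#' @export
met_params <- function(blh_mean = 600, blh_noise = 0.35, blh_phi = 0.7,
                       bld_mean = 250, bld_noise = 0.5, bld_phi = 0.6,
                       p_wet = 0.35, precip_mean = 4e-3, precip_noise = 1,
                       u_mean = 1.5, v_mean = 0.5, wind_noise = 1.2,
                       wind_phi = 0.6,
                       t_mean = 13.5, t_amp = 6, t_noise = 1.5, t_phi = 0.8,
                       dew_depression = 2.5,
                       sp_mean = 101325, sp_noise = 700,
                       tcc_mean = 0.6, tcc_noise = 0.15,
                       ssr_mean = 1.2e7, ssr_noise = 0.3,
                       spatial_noise = 0.08) {
  as.list(environment())
}

#' Simulate daily meteorology at the nine grid points
#'
#' The centre series are autoregressive: positive variables (boundary-layer
#' height and dissipation) are lognormal AR(1), winds and temperature Gaussian
#' AR(1) about their mean paths, precipitation an occurrence x gamma-amount
#' process with the mean precipitation rate derived exactly from the daily
#' total. The 8 surrounding points are the centre series plus small spatially
#' coherent perturbations (a fixed per-point offset plus slow AR(1) noise).
#'
#' @param days number of days (>= 1).
#' @param seed integer seed.
#' @param params a [met_params()].
#' @param start first date (UTC day).
#' @return a [met_table()] with 12 variables x 9 points per day.
#' @export
simulate_met <- function(days, seed = 1, params = met_params(),
                         start = as.Date("2021-07-01")) {
  stopifnot(days >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- params
  dates <- seq(as.Date(start), by = "day", length.out = days)
  doy <- as.integer(format(dates, "%j"))
  season <- sin(2 * pi * (doy - 105) / 365.25)

  blh <- p$blh_mean * exp(.ar1(days, p$blh_phi, p$blh_noise))
  bld <- p$bld_mean * exp(.ar1(days, p$bld_phi, p$bld_noise))
  if (p$precip_noise == 0) {
    tp <- rep(p$p_wet * p$precip_mean, days)
  } else {
    wet <- rbinom(days, 1, p$p_wet)
    amt <- rgamma(days, shape = 0.8, scale = p$precip_mean / 0.8)
    tp <- wet * amt * p$precip_noise
  }
  mtpr <- tp * 1000 / 86400 # m/day -> kg m-2 s-1
  u10 <- p$u_mean + .ar1(days, p$wind_phi, p$wind_noise)
  v10 <- p$v_mean + .ar1(days, p$wind_phi, p$wind_noise)
  t2m <- p$t_mean + p$t_amp * season + .ar1(days, p$t_phi, p$t_noise)
  d2m <- t2m - pmax(0.2, p$dew_depression + .ar1(days, 0.5, p$t_noise / 2))
  sp <- p$sp_mean + .ar1(days, 0.7, p$sp_noise)
  tcc <- pmin(1, pmax(0, p$tcc_mean + .ar1(days, 0.5, p$tcc_noise)))
  spd <- sqrt(u10^2 + v10^2)
  fg10 <- 1.6 * spd + abs(.ar1(days, 0.3, p$wind_noise / 2))
  ssr <- pmax(0, p$ssr_mean * (0.55 + 0.45 * season) *
                exp(.ar1(days, 0.4, p$ssr_noise)))

  centre <- list(blh = blh, bld = bld, tp = tp, mtpr = mtpr, u10 = u10,
                 v10 = v10, t2m = t2m, d2m = d2m, sp = sp, tcc = tcc,
                 fg10 = fg10, ssr = ssr)
  multiplicative <- c("blh", "bld", "tp", "mtpr", "fg10", "ssr")
  rows <- vector("list", length(centre) * length(MET_POINTS))
  i <- 0L
  for (vn in names(centre)) {
    for (pt in MET_POINTS) {
      val <- centre[[vn]]
      if (pt != "C" && p$spatial_noise > 0) {
        pert <- rnorm(1, 0, p$spatial_noise) +
          .ar1(days, 0.8, p$spatial_noise / 2)
        val <- if (vn %in% multiplicative) val * exp(pert) else {
          scale <- max(sd(val), abs(mean(val)) * 0.05, 1e-8)
          val + scale * pert
        }
        if (vn == "tcc") val <- pmin(1, pmax(0, val))
      }
      i <- i + 1L
      rows[[i]] <- data.frame(date = dates, point = pt, variable = vn,
                              value = val)
    }
  }
  met_table(do.call(rbind, rows))
}

# relative humidity (%) from temperature and dewpoint via the Magnus formula
.rh_from_dewpoint <- function(t2m, d2m) {
  a <- 17.625; b <- 243.04
  pmin(100, 100 * exp(a * d2m / (b + d2m) - a * t2m / (b + t2m)))
}

# pull one variable's centre-point series aligned to `dates`
.met_centre <- function(met, var, dates) {
  sub <- met[met$point == "C" & met$variable == var, ]
  idx <- match(dates, sub$date)
  if (anyNA(idx)) stop("coverage error: met data does not cover all dates")
  sub$value[idx]
}

#' Simulate the latent PM field and the monitor truth series
#'
#' Total concentration at location x on day t is
#' `C(x,t) = (B(t) * (1 + g(x)) + sum_cat alpha_cat * rho_cat(x) *
#' (blh_ref / BLH(t)) * exp(-kappa * precip(t))) * eps(t)`, where `g(x)` is the
#' town's smooth background surface (a Gaussian elevation over the town centre
#' emulating the spread secondary/urban-background component of real PM
#' fields), `rho_cat` is the category road density (vertex counts in a 200 m
#' window of the 4 m raster, the features module's definition), BLH dilutes
#' road sources, precipitation washes them out, and `eps(t)` is day-level
#' lognormal noise shared across space (so the field remains exactly evaluable
#' at any location). Size-resolved series are cumulative shares of the total
#' mass.
#'
#' @param town a [make_town()] result.
#' @param met a [met_table()] covering the requested dates.
#' @param noise_sd standard deviation of `log eps` (0 = noise-free).
#' @param seed integer seed.
#' @param raster_res road raster resolution (m).
#' @param window road-density window side (m).
#' @return list with `truth_field(x, y, size)` returning a days x points
#'   matrix, `monitor_truth` (list of daily [monitor_series()] with
#'   temperature and humidity from the centre met point), `dates`, and the
#'   internal `components` (background, dilution factor, day noise, road term
#'   per monitor).
#' @export
simulate_pm <- function(town, met, noise_sd = 0.1, seed = 1,
                        raster_res = 4, window = 200) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dates <- sort(unique(met$date))
  days <- length(dates)
  blh <- .met_centre(met, "blh", dates)
  tp <- .met_centre(met, "tp", dates)
  t2m <- .met_centre(met, "t2m", dates)
  d2m <- .met_centre(met, "d2m", dates)
  f_t <- (town$blh_ref / blh) * exp(-town$kappa * tp)
  bg <- town$background_mean *
    exp(.ar1(days, town$background_phi, town$background_sdlog))
  eps <- if (noise_sd == 0) rep(1, days) else exp(rnorm(days, 0, noise_sd))

  raster <- rasterize_roads(town$roads, resolution = raster_res)
  frac <- town$size_fractions
  alpha <- town$alpha[road_category_names()]
  alpha[is.na(alpha)] <- 0
  road_term_at <- function(x, y) {
    dens <- road_density(raster, cbind(x, y), window = window)
    as.numeric(dens %*% alpha) # columns follow the fixed category order
  }
  bg_amp <- if (is.null(town$bg_amp)) 0 else town$bg_amp
  bg_scale <- if (is.null(town$bg_scale)) 1 else town$bg_scale
  bg_surface_at <- function(x, y) {
    d2 <- (x - town$centre[1])^2 + (y - town$centre[2])^2
    1 + bg_amp * exp(-d2 / (2 * bg_scale^2))
  }
  truth_field <- function(x, y, size = c("pm25", "pm1", "pm10")) {
    size <- match.arg(size)
    road <- road_term_at(x, y)
    m <- outer(bg * eps, bg_surface_at(x, y)) + outer(f_t * eps, road)
    m * frac[[size]]
  }
  rh <- .rh_from_dewpoint(t2m, d2m)
  monitor_truth <- lapply(seq_len(nrow(town$monitors)), function(i) {
    mrow <- town$monitors[i, ]
    road <- road_term_at(mrow$x, mrow$y)
    total <- (bg * bg_surface_at(mrow$x, mrow$y) + road * f_t) * eps
    ms <- monitor_series(
      tibble::tibble(
        time = dates,
        pm1 = total * frac[["pm1"]],
        pm25 = total * frac[["pm25"]],
        pm10 = total * frac[["pm10"]],
        temperature = t2m, relative_humidity = rh
      ),
      station_id = mrow$station_id, latitude = mrow$lat,
      longitude = mrow$lon, step = "day"
    )
    attr(ms, "x") <- mrow$x
    attr(ms, "y") <- mrow$y
    ms
  })
  names(monitor_truth) <- town$monitors$station_id
  list(
    truth_field = truth_field, monitor_truth = monitor_truth, dates = dates,
    components = list(background = bg, dilution = f_t, day_noise = eps,
                      road_term = vapply(
                        seq_len(nrow(town$monitors)),
                        function(i) road_term_at(town$monitors$x[i],
                                                 town$monitors$y[i]),
                        numeric(1)))
  )
}

#' Distort a truth series into raw low-cost-sensor readings
#'
#' Emulates the bias of optical particle counters: an offset, a gain, a mild
#' quadratic term and a humidity-growth cross term, plus Gaussian noise:
#' `raw = a0 + a1*pm + a2*pm^2 + b1*RH*pm + N(0, noise_sd)`, applied to each
#' size class. The distortion parameters are stored as an attribute so
#' calibration recovery is checkable.
#'
#' @param truth a [monitor_series()] with temperature and humidity populated.
#' @param params list with `a0`, `a1`, `a2`, `b1`, `noise_sd`.
#' @param seed integer seed.
#' @return a raw `monitor_series` with attribute `distortion`.
#' @export
distort_sensor <- function(truth,
                           params = list(a0 = 2, a1 = 0.8, a2 = 0.004,
                                         b1 = 0.002, noise_sd = 1),
                           seed = 1) {
  if (all(is.na(truth$relative_humidity))) {
    stop("truth series must have relative humidity populated")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- tibble::as_tibble(as.data.frame(truth))
  rh <- out$relative_humidity
  for (col in c("pm1", "pm25", "pm10")) {
    v <- out[[col]]
    noise <- if (params$noise_sd == 0) 0 else rnorm(length(v), 0, params$noise_sd)
    raw <- params$a0 + params$a1 * v + params$a2 * v^2 + params$b1 * rh * v +
      noise
    out[[col]] <- pmax(0, raw)
  }
  res <- monitor_series(out, attr(truth, "station_id"),
                        attr(truth, "latitude"), attr(truth, "longitude"),
                        step = attr(truth, "step"))
  attr(res, "x") <- attr(truth, "x")
  attr(res, "y") <- attr(truth, "y")
  attr(res, "distortion") <- params
  res
}

#' Simulate a colocation (calibration) dataset
#'
#' Emulates a colocation campaign of a low-cost sensor against a reference
#' instrument: reference concentrations spanning a wide ambient range
#' (lognormal, roughly 2-40 ug/m3), temperature and humidity varying over
#' realistic spans, and raw sensor readings produced by [distort_sensor()].
#'
#' @param n number of paired observations (days).
#' @param seed integer seed.
#' @param params distortion parameters, as in [distort_sensor()].
#' @param level_meanlog,level_sdlog lognormal parameters of the reference
#'   concentration range.
#' @return list with `reference` and `raw` [monitor_series()] (station id
#'   "colocation").
#' @export
simulate_colocation <- function(n = 200, seed = 1,
                                params = list(a0 = 2, a1 = 0.8, a2 = 0.004,
                                              b1 = 0.002, noise_sd = 1),
                                level_meanlog = log(10), level_sdlog = 0.5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  total <- exp(rnorm(n, level_meanlog, level_sdlog))
  temperature <- runif(n, 2, 28)
  rh <- runif(n, 40, 98)
  frac <- c(pm1 = 0.90, pm25 = 0.97, pm10 = 1.00)
  reference <- monitor_series(
    tibble::tibble(
      time = seq(as.Date("2021-01-01"), by = "day", length.out = n),
      pm1 = total * frac[["pm1"]], pm25 = total * frac[["pm25"]],
      pm10 = total * frac[["pm10"]],
      temperature = temperature, relative_humidity = rh
    ),
    station_id = "colocation", latitude = NA_real_, longitude = NA_real_,
    step = "day"
  )
  raw <- distort_sensor(reference, params = params, seed = seed + 1L)
  list(reference = reference, raw = raw)
}

#' Write a simulated town to disk
#'
#' Produces the file set the readers consume: per-monitor CSVs, a station
#' table, a long-format met CSV, a roads GeoJSON and a JSON manifest of all
#' generator parameters.
#'
#' @param town a [make_town()] result.
#' @param met a [met_table()].
#' @param sim a [simulate_pm()] result (truth or distorted series may be
#'   written by passing them via `series`).
#' @param dir output directory (created if needed).
#' @param series list of [monitor_series()] to write; defaults to
#'   `sim$monitor_truth`.
#' @return `dir`, invisibly.
#' @export
write_town <- function(town, met, sim, dir, series = sim$monitor_truth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ms in series) {
    write_monitor_csv(ms, file.path(dir, paste0(
      "monitor_", attr(ms, "station_id"), ".csv")))
  }
  st <- town$monitors
  write.csv(
    data.frame(station_id = st$station_id, lat = st$lat, lon = st$lon),
    file.path(dir, "stations.csv"), row.names = FALSE, quote = FALSE
  )
  write_met_csv(met, file.path(dir, "met.csv"))
  write_roads_geojson(town$roads, file.path(dir, "roads.geojson"),
                      anchor = town$anchor)
  manifest <- list(
    domain = town$domain, anchor = town$anchor, seed = town$seed,
    alpha = as.list(town$alpha),
    background_mean = town$background_mean,
    background_sdlog = town$background_sdlog,
    background_phi = town$background_phi,
    blh_ref = town$blh_ref, kappa = town$kappa,
    size_fractions = as.list(town$size_fractions),
    monitors = town$monitors
  )
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(dir)
}
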