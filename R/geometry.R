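#' Local planar coordinate frames
#'
#' The pipeline does all geometry in a local planar frame: metres east (x) and
#' north (y) of a WGS84 anchor point. At town scale (~10 km) an equirectangular
#' projection about the anchor is accurate to well under a metre, keeps
#' distances Euclidean and avoids a projection-library dependency.
#'
#' @param anchor numeric length-2, c(lon, lat) of the frame origin (degrees).
#' @param lon,lat numeric vectors of geographic coordinates (degrees).
#' @param x,y numeric vectors of local coordinates (metres).
#' @return `lonlat_to_local` returns a two-column matrix (x, y) in metres;
#'   `local_to_lonlat` the inverse, a two-column matrix (lon, lat).
#' @name local_frame
NULL

.EARTH_RADIUS_M <- 6371000

#' @rdname local_frame
#' @export
lonlat_to_local <- function(lon, lat, anchor) {
  stopifnot(length(anchor) == 2, is.finite(anchor))
  deg <- pi / 180
  x <- (lon - anchor[1]) * cos(anchor[2] * deg) * .EARTH_RADIUS_M * deg
  y <- (lat - anchor[2]) * .EARTH_RADIUS_M * deg
  cbind(x = x, y = y)
}

#' @rdname local_frame
#' @export
local_to_lonlat <- function(x, y, anchor) {
  stopifnot(length(anchor) == 2, is.finite(anchor))
  deg <- pi / 180
  lon <- anchor[1] + x / (cos(anchor[2] * deg) * .EARTH_RADIUS_M * deg)
  lat <- anchor[2] + y / (.EARTH_RADIUS_M * deg)
  cbind(lon = lon, lat = lat)
}

#' Distance and bearing between two points
#'
#' For planar inputs (the default) the distance is Euclidean and the bearing is
#' measured clockwise from grid north. For geographic inputs the distance is the
#' haversine great-circle distance on a sphere of radius 6371 km and the
#' bearing is the initial great-circle bearing. Coincident points return
#' distance 0 and bearing 0 by convention.
#'
#' @param p,q numeric length-2 points: c(x, y) metres for planar input,
#'   c(lon, lat) degrees for geographic input.
#' @param geographic logical; interpret inputs as lon/lat degrees?
#' @return named numeric vector c(distance = metres, bearing = degrees in
#'   [0, 360)).
#' @export
distance_and_bearing <- function(p, q, geographic = FALSE) {
  stopifnot(length(p) == 2, length(q) == 2)
  if (!geographic) {
    dx <- q[1] - p[1]
    dy <- q[2] - p[2]
    d <- sqrt(dx^2 + dy^2)
    b <- if (d == 0) 0 else (atan2(dx, dy) * 180 / pi) %% 360
    return(c(distance = unname(d), bearing = unname(b)))
  }
  deg <- pi / 180
  lam1 <- p[1] * deg; phi1 <- p[2] * deg
  lam2 <- q[1] * deg; phi2 <- q[2] * deg
  dphi <- phi2 - phi1
  dlam <- lam2 - lam1
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  d <- 2 * .EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
  if (d == 0) return(c(distance = 0, bearing = 0))
  ybrg <- sin(dlam) * cos(phi2)
  xbrg <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  b <- (atan2(ybrg, xbrg) * 180 / pi) %% 360
  c(distance = unname(d), bearing = unname(b))
}

#' Meteorological wind-from direction
#'
#' Converts wind vector components into the direction the wind blows from,
#' in degrees clockwise from north (0 = northerly wind, 90 = easterly).
#'
#' @param u eastward wind component (m/s).
#' @param v northward wind component (m/s).
#' @return degrees in [0, 360); NA where both components are 0.
#' @export
wind_from_direction <- function(u, v) {
  out <- (atan2(-u, -v) * 180 / pi) %% 360
  out[u == 0 & v == 0] <- NA_real_
  out
}
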