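#' Oblique Mercator projection centred on a study origin
#'
#' Projects geographic coordinates into a conformal oblique Mercator plane
#' whose origin is a chosen centre point (default 35.0N, 75.0W, the
#' conventional origin for Middle Atlantic Bight telemetry work). The
#' projection is built by rotating the sphere so the centre maps to the
#' rotated equator, then applying the standard Mercator map; it is
#' length-true along the central line through the centre, so distances over
#' a continental-shelf study area are preserved to well under 0.1%.
#'
#' @param lon,lat numeric vectors of geographic coordinates (degrees).
#' @param center length-2 numeric, \code{c(lon, lat)} of the projection
#'   centre (degrees).
#' @param azimuth azimuth of the central line at the centre, degrees
#'   clockwise from north. The default 90 runs the central line east-west.
#' @return A tibble with columns \code{x}, \code{y} in metres
#'   (\code{project_coordinates}) or \code{lon}, \code{lat} in degrees
#'   (\code{unproject_coordinates}). The centre maps to (0, 0).
#' @examples
#' project_coordinates(-75, 35)           # exactly (0, 0)
#' unproject_coordinates(10000, 10000)
#' @export
project_coordinates <- function(lon, lat, center = c(-75, 35), azimuth = 90) {
  assert_that(length(lon) == length(lat), "lon and lat must have equal length")
  assert_that(all(is.finite(lon)) && all(is.finite(lat)),
              "coordinates must be finite")
  assert_that(all(abs(lat) <= 90), "latitude must lie in [-90, 90]")
  if (any(abs(lat) > 89.999))
    stop_bt("geographic poles cannot be projected: pole/antipode failure")
  M <- oblique_rotation(center, azimuth)
  rad <- pi / 180
  cl <- cos(lat * rad)
  p <- cbind(cl * cos(lon * rad), cl * sin(lon * rad), sin(lat * rad))
  q <- p %*% t(M)
  # q[,1] is the cosine of the angular distance from the centre
  lat_r <- asin(pmin(1, pmax(-1, q[, 3])))
  bad <- abs(lat_r) > (89.5 * rad) | q[, 1] < cos(179.5 * rad)
  if (any(bad))
    stop_bt("points at or near the projection poles/antipode cannot be projected")
  lon_r <- atan2(q[, 2], q[, 1])
  tibble::tibble(x = BT_EARTH_RADIUS * lon_r,
                 y = BT_EARTH_RADIUS * atanh(sin(lat_r)))
}

#' @rdname project_coordinates
#' @param x,y numeric vectors of projected coordinates (metres).
#' @export
unproject_coordinates <- function(x, y, center = c(-75, 35), azimuth = 90) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "coordinates must be finite")
  lon_r <- x / BT_EARTH_RADIUS
  assert_that(all(abs(lon_r) <= pi), "x outside the projectable range")
  lat_r <- asin(tanh(y / BT_EARTH_RADIUS))
  q <- cbind(cos(lat_r) * cos(lon_r), cos(lat_r) * sin(lon_r), sin(lat_r))
  M <- oblique_rotation(center, azimuth)
  p <- q %*% M
  rad <- pi / 180
  tibble::tibble(lon = atan2(p[, 2], p[, 1]) / rad,
                 lat = asin(pmin(1, pmax(-1, p[, 3]))) / rad)
}

# Rotation matrix taking the geographic unit sphere to oblique coordinates:
# row 1 = centre direction, row 2 = central-line tangent (azimuth at the
# centre), row 3 = their cross product (oblique pole).
oblique_rotation <- function(center, azimuth) {
  rad <- pi / 180
  lam <- center[1] * rad
  phi <- center[2] * rad
  a <- azimuth * rad
  c0 <- c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  north <- c(-sin(phi) * cos(lam), -sin(phi) * sin(lam), cos(phi))
  east <- c(-sin(lam), cos(lam), 0)
  t0 <- cos(a) * north + sin(a) * east
  M <- rbind(c0, t0, c(c0[2] * t0[3] - c0[3] * t0[2],
                       c0[3] * t0[1] - c0[1] * t0[3],
                       c0[1] * t0[2] - c0[2] * t0[1]))
  dimnames(M) <- NULL
  M
}
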