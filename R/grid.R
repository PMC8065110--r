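#' Build a uniform projected study grid
#'
#' Lays a regular lattice of square cells (default 10 km, the resolution of
#' the assessment grid used for Northwest Atlantic protected-species work)
#' over the projected bounding box of a geographic extent, and synthesises a
#' parametric coastline so that cells north-west of it are flagged land.
#'
#' @param lon_range,lat_range length-2 numeric extents in degrees.
#' @param cell_size cell edge length in metres.
#' @param coast coastline description from [coast_line()], or `NULL` for an
#'   all-ocean grid.
#' @param center,azimuth projection parameters passed to
#'   [project_coordinates()].
#' @return An `env_grid`: a tibble with one row per cell and columns
#'   `cell_id`, `ix`, `iy`, `x_center`, `y_center`, `lon_center`,
#'   `lat_center`, `depth` (NA until [make_bathymetry()] fills it),
#'   `land_mask`, `shelf_mask` (NA until [apply_study_mask()]). Grid
#'   geometry (origin, cell size, dimensions) is stored in attributes.
#' @export
make_grid <- function(lon_range, lat_range, cell_size = 10000,
                      coast = coast_line(), center = c(-75, 35),
                      azimuth = 90) {
  assert_that(cell_size > 0, "cell_size must be positive")
  assert_that(diff(range(lon_range)) > 0 && diff(range(lat_range)) > 0,
              "degenerate grid extent")
  corners <- project_coordinates(
    lon = c(lon_range[1], lon_range[2], lon_range[1], lon_range[2]),
    lat = c(lat_range[1], lat_range[1], lat_range[2], lat_range[2]),
    center = center, azimuth = azimuth)
  x0 <- min(corners$x); y0 <- min(corners$y)
  nx <- max(1L, as.integer(round((max(corners$x) - x0) / cell_size)))
  ny <- max(1L, as.integer(round((max(corners$y) - y0) / cell_size)))
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  xc <- x0 + (ix - 0.5) * cell_size
  yc <- y0 + (iy - 0.5) * cell_size
  ll <- unproject_coordinates(xc, yc, center = center, azimuth = azimuth)
  land <- if (is.null(coast)) rep(FALSE, nx * ny) else
    ll$lat > coast_latitude(coast, ll$lon)
  g <- tibble::tibble(
    cell_id = seq_len(nx * ny), ix = ix, iy = iy,
    x_center = xc, y_center = yc,
    lon_center = ll$lon, lat_center = ll$lat,
    depth = NA_real_, land_mask = land, shelf_mask = NA)
  structure(g, class = c("env_grid", class(g)),
            cell_size = cell_size, x0 = x0, y0 = y0, nx = nx, ny = ny,
            center = center, azimuth = azimuth, coast = coast)
}

#' Parametric coastline
#'
#' The coastline is a longitude-dependent latitude curve: cells with centre
#' latitude above it are land. The default runs roughly south-west to
#' north-east like the US Atlantic seaboard between Cape Hatteras and the
#' Gulf of Maine.
#'
#' @param lat_at_lon0 coastline latitude (degrees) at `lon0`.
#' @param lon0 reference longitude (degrees).
#' @param slope degrees of coastline latitude per degree of longitude.
#' @param amplitude,wavelength optional sinusoidal wiggle (degrees).
#' @export
coast_line <- function(lat_at_lon0 = 35.5, lon0 = -75, slope = 1.2,
                       amplitude = 0, wavelength = 5) {
  list(lat_at_lon0 = lat_at_lon0, lon0 = lon0, slope = slope,
       amplitude = amplitude, wavelength = wavelength)
}

coast_latitude <- function(coast, lon) {
  coast$lat_at_lon0 + coast$slope * (lon - coast$lon0) +
    coast$amplitude * sin(2 * pi * (lon - coast$lon0) / coast$wavelength)
}

#' Synthetic shelf bathymetry
#'
#' Fills the grid's `depth` column with a deterministic offshore ramp plus
#' optional Gaussian noise: depth grows linearly with distance from the
#' coastline (measured as degrees of latitude south of the coast curve,
#' converted to km) until it saturates at `max_depth`. Land cells get depth
#' 0. This stands in for a gridded relief product; only the monotone
#' shoreline-to-slope structure matters to the pipeline.
#'
#' @param grid an `env_grid`.
#' @param slope list with `rate` (metres of depth per km offshore),
#'   `max_depth` (metres, ramp saturation) and optional `widen_north`
#'   (>= 0): the bottom slope is divided by
#'   `1 + widen_north * (lat - lat_min) / (lat_max - lat_min)`, so the
#'   shelf broadens towards the north the way the Middle Atlantic Bight
#'   gives way to the wide Southern New England / Georges Bank shelf.
#' @param noise_sd standard deviation of additive depth noise (m).
#' @param seed integer seed for the noise; `NULL` uses the ambient RNG.
#' @return the grid with `depth` populated (>= 0 on water, 0 on land).
#' @export
make_bathymetry <- function(grid,
                            slope = list(rate = 4, max_depth = 320,
                                         widen_north = 2.5),
                            noise_sd = 0, seed = NULL) {
  assert_that(inherits(grid, "env_grid"), "grid must be an env_grid")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  coast <- attr(grid, "coast")
  ref_lat <- if (is.null(coast)) max(grid$lat_center) else
    coast_latitude(coast, grid$lon_center)
  s_km <- pmax(0, (ref_lat - grid$lat_center)) * BT_M_PER_DEG / 1000
  wn <- slope$widen_north %||% 0
  lat <- grid$lat_center
  widen <- if (wn > 0 && diff(range(lat)) > 0)
    1 + wn * (lat - min(lat)) / diff(range(lat)) else 1
  depth <- pmin(slope$max_depth, slope$rate * s_km / widen)
  if (noise_sd > 0)
    depth <- with_seed(seed, pmax(0, depth + stats::rnorm(length(depth), 0, noise_sd)))
  depth[grid$land_mask] <- 0
  grid$depth <- depth
  grid
}

#' Shelf study mask
#'
#' Marks the modelling domain: water cells shallower than `max_depth`
#' (strict inequality) with centre latitude inside `lat_band` (inclusive).
#' The defaults reproduce the continental-shelf study band: depths < 200 m
#' between 33.5N and 41.6N.
#'
#' @param grid an `env_grid` with depth populated.
#' @param lat_band length-2 latitude band (degrees).
#' @param max_depth depth cut-off in metres; cells at exactly `max_depth`
#'   are excluded.
#' @return the grid with `shelf_mask` populated.
#' @export
apply_study_mask <- function(grid, lat_band = c(33.5, 41.6), max_depth = 200) {
  assert_that(inherits(grid, "env_grid"), "grid must be an env_grid")
  assert_that(all(is.finite(grid$depth)), "grid depth must be set first")
  mask <- !grid$land_mask & grid$depth < max_depth &
    grid$lat_center >= lat_band[1] & grid$lat_center <= lat_band[2]
  if (!any(mask)) stop_bt("study mask is empty: no shelf cells in the extent")
  grid$shelf_mask <- mask
  grid
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells of %.0f m (%d land, %s shelf)\n",
              attr(x, "nx"), attr(x, "ny"), attr(x, "cell_size"),
              sum(x$land_mask),
              if (all(is.na(x$shelf_mask))) "unmasked" else sum(x$shelf_mask)))
  NextMethod()
}
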