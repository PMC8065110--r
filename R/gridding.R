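#' Aggregate daily positions onto the grid by month
#'
#' Assigns projected daily positions to grid cells using half-open cell
#' intervals `[edge, edge + cell_size)` on both axes, and bins them by
#' calendar year and month. Positions outside the grid extent are dropped
#' with a message.
#'
#' @param daily_positions data frame with columns `date` (Date), `x`, `y`
#'   (m), e.g. stacked [interpolate_daily()] outputs.
#' @param grid an `env_grid`.
#' @return a `presence_counts` tibble: `cell_id`, `year`, `month`,
#'   `n_positions` (one row per occupied cell-month); the number of dropped
#'   positions is in `attr(, "n_dropped")`.
#' @export
assign_cells <- function(daily_positions, grid) {
  cs <- attr(grid, "cell_size")
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  ix <- floor((daily_positions$x - attr(grid, "x0")) / cs) + 1
  iy <- floor((daily_positions$y - attr(grid, "y0")) / cs) + 1
  inside <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  n_dropped <- sum(!inside)
  if (n_dropped > 0)
    message(n_dropped, " position(s) outside the grid extent were dropped")
  d <- daily_positions[inside, , drop = FALSE]
  cell <- (iy[inside] - 1) * nx + ix[inside]
  yr <- as.integer(format(d$date, "%Y"))
  mo <- as.integer(format(d$date, "%m"))
  agg <- stats::aggregate(list(n_positions = rep(1L, length(cell))),
                          by = list(cell_id = cell, year = yr, month = mo),
                          FUN = sum)
  out <- tibble::as_tibble(agg[order(agg$cell_id, agg$year, agg$month), ])
  structure(out, class = c("presence_counts", class(out)),
            n_dropped = n_dropped)
}

#' Regrid a coarse monthly SST product onto the grid
#'
#' Maps a coarse-resolution monthly SST field (e.g. a 1/4-degree blended
#' satellite product) to the grid cells by unweighted averaging of all
#' coarse pixels whose centres fall inside each cell; cells containing no
#' pixel centre take the value of the nearest pixel (projected distance).
#'
#' @param source data frame of coarse pixel centres with columns `lon`,
#'   `lat`, `month` (1-12), `sst` (degC).
#' @param grid an `env_grid`.
#' @return an `sst_clim` matrix (cells x 12).
#' @export
monthly_sst <- function(source, grid) {
  assert_that(all(c("lon", "lat", "month", "sst") %in% names(source)),
              "source needs columns lon, lat, month, sst")
  cs <- attr(grid, "cell_size")
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  pts <- unique(source[, c("lon", "lat")])
  xy <- project_coordinates(pts$lon, pts$lat, center = attr(grid, "center"),
                            azimuth = attr(grid, "azimuth"))
  pts$px <- xy$x; pts$py <- xy$y
  ix <- floor((pts$px - attr(grid, "x0")) / cs) + 1
  iy <- floor((pts$py - attr(grid, "y0")) / cs) + 1
  pts$cell <- ifelse(ix >= 1 & ix <= nx & iy >= 1 & iy <= ny,
                     (iy - 1) * nx + ix, NA_integer_)
  src <- merge(source, pts, by = c("lon", "lat"))
  out <- matrix(NA_real_, nrow(grid), 12)
  for (m in 1:12) {
    sm <- src[src$month == m & is.finite(src$sst), , drop = FALSE]
    if (nrow(sm) == 0) stop_bt("source month ", m, " has no usable SST values")
    means <- tapply(sm$sst, sm$cell, mean)
    hit <- as.integer(names(means))
    out[hit, m] <- as.numeric(means)
    empty <- which(is.na(out[, m]))
    if (length(empty)) {
      # nearest coarse pixel in projected coordinates
      nn <- vapply(empty, function(ci) {
        which.min((sm$px - grid$x_center[ci])^2 + (sm$py - grid$y_center[ci])^2)
      }, integer(1))
      out[empty, m] <- sm$sst[nn]
    }
  }
  colnames(out) <- month.abb
  structure(out, class = c("sst_clim", "matrix", "array"))
}

#' Build the cell-by-month occurrence table
#'
#' One row per shelf cell per study month: `y = 1` where at least one daily
#' position fell in the cell that month, `y = 0` otherwise (absence by
#' omission over the gridded study domain), with the monthly SST and the
#' cell depth as covariates. Presences outside the shelf mask are excluded;
#' rows with missing covariates are dropped with their count recorded.
#'
#' @param presences a `presence_counts` table from [assign_cells()], or any
#'   data frame with `cell_id`, `year`, `month`.
#' @param grid an `env_grid` with the shelf mask applied.
#' @param sst_by_month an `sst_clim` matrix (cells x 12; calendar-month
#'   climatology shared across study years) or a 3-d array
#'   (cells x 12 x years) for per year-month fields.
#' @param study_years integer vector of study years (defaults to the years
#'   present in `presences`).
#' @param months calendar months making up the study period.
#' @return an `occurrence_table` tibble (`cell_id`, `year`, `month`, `y`,
#'   `sst_c`, `depth_m`); dropped-row count in `attr(, "n_dropped")`.
#' @export
build_occurrence_table <- function(presences, grid, sst_by_month,
                                   study_years = NULL, months = 1:12) {
  assert_that(any(grid$shelf_mask %in% TRUE),
              "grid has no shelf cells; run apply_study_mask() first")
  if (is.null(study_years)) study_years <- sort(unique(presences$year))
  assert_that(length(study_years) >= 1, "no study years")
  shelf <- which(grid$shelf_mask)
  base <- expand.grid(cell = shelf, month = as.integer(months),
                      year = as.integer(study_years))
  per_year <- length(dim(sst_by_month)) == 3
  if (per_year) {
    yi <- match(base$year, study_years)
    sst <- sst_by_month[cbind(base$cell, base$month, yi)]
  } else {
    sst <- sst_by_month[cbind(base$cell, base$month)]
  }
  key <- paste(base$cell, base$year, base$month)
  pk <- paste(presences$cell_id, presences$year, presences$month)
  tab <- tibble::tibble(cell_id = grid$cell_id[base$cell],
                        year = base$year, month = base$month,
                        y = as.integer(key %in% pk),
                        sst_c = sst, depth_m = grid$depth[base$cell])
  ok <- is.finite(tab$sst_c) & is.finite(tab$depth_m)
  n_dropped <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]
  if (sum(tab$y) == 0)
    stop_bt("no presences fall inside the shelf mask: model unidentifiable")
  tab <- tab[order(tab$year, tab$month, tab$cell_id), ]
  structure(tab, class = c("occurrence_table", class(tab)),
            n_dropped = n_dropped)
}

#' Observed covariate envelope at presences
#'
#' The range of SST and depth over the presence rows of an occurrence
#' table: a descriptive occupancy envelope complementary to the model-based
#' [core_habitat_envelope()].
#'
#' @param table an `occurrence_table`.
#' @return list with `sst` and `depth` ranges.
#' @export
presence_envelope <- function(table) {
  pres <- table[table$y == 1, ]
  assert_that(nrow(pres) > 0, "table has no presences")
  list(sst = range(pres$sst_c), depth = range(pres$depth_m))
}
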