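#' Add climate-model deltas to the observed climatology
#'
#' Elementwise sum of the observed monthly mean SST and the projected
#' deviation for a given projection year and month (the climate-delta
#' method); depth is untouched throughout the projection.
#'
#' @param climatology an `sst_clim` (cells x 12).
#' @param deltas a `delta_series` (cells x 12 x years).
#' @param year projection year index (1-based).
#' @param month calendar month (1-12).
#' @return numeric vector of projected SST per cell (degC).
#' @export
apply_deltas <- function(climatology, deltas, year, month) {
  assert_that(nrow(climatology) == dim(deltas)[1] && dim(deltas)[2] == 12,
              "climatology and deltas are not aligned")
  assert_that(month %in% 1:12, "month must be in 1..12")
  assert_that(year >= 1 && year <= dim(deltas)[3],
              "year outside the projection horizon")
  climatology[, month] + deltas[, month, year]
}

#' Project occupancy probability over the horizon
#'
#' For every shelf cell, calendar month and projection year, predicts the
#' probability of presence from the fitted model at the delta-shifted SST
#' and the (constant) cell depth, and classifies occupancy at the cut-point
#' `c`. Non-shelf cells are missing, never absent.
#'
#' @param fit a `habitat_fit` (or `truth_surface`).
#' @param climatology an `sst_clim`.
#' @param deltas a `delta_series`.
#' @param grid the `env_grid` (shelf mask applied).
#' @param c occupancy cut-point in `[0, 1]`.
#' @param horizon number of projection years to emit (<= delta horizon).
#' @return an `occupancy_projection`: list with `probability` and
#'   `occupancy` arrays (cells x 12 x horizon), `sst` (projected SST
#'   array), `cutpoint`, and the grid geometry in attributes.
#' @export
project_occupancy <- function(fit, climatology, deltas, grid, c,
                              horizon = dim(deltas)[3]) {
  assert_that(horizon >= 1 && horizon <= dim(deltas)[3],
              "horizon must be within the delta series")
  assert_that(any(grid$shelf_mask %in% TRUE), "grid has no shelf cells")
  if (inherits(fit, "habitat_fit") && !fit$converged)
    warning("projecting from a non-converged fit")
  n_cell <- nrow(grid)
  shelf <- grid$shelf_mask
  sst <- array(NA_real_, c(n_cell, 12, horizon))
  clim_block <- array(climatology, c(n_cell, 12, horizon))
  sst[] <- clim_block + deltas[, , seq_len(horizon), drop = FALSE]
  prob <- array(NA_real_, c(n_cell, 12, horizon))
  ps <- predict_probability(fit, sst[shelf, , , drop = FALSE],
                            array(grid$depth[shelf], c(sum(shelf), 12, horizon)))
  prob[shelf, , ] <- ps
  occ <- classify_occupancy(prob, c)
  structure(list(probability = prob, occupancy = occ, sst = sst,
                 cutpoint = c, horizon = horizon),
            class = "occupancy_projection", shelf_mask = shelf,
            n_shelf = sum(shelf))
}

bt_season_map <- function() {
  list(winter = 1:3, spring = 4:6, summer = 7:9, fall = 10:12)
}

#' Seasonal and decadal occupancy summaries
#'
#' Averages projected probability fields within seasons (winter = Jan-Mar,
#' spring = Apr-Jun, summer = Jul-Sep, fall = Oct-Dec by default) and
#' year bins, then computes the occupied fraction of shelf cells. Bin 0 is
#' the observed (zero-delta) era predicted from the climatology itself.
#'
#' @param projection an `occupancy_projection`.
#' @param fit,climatology,grid the fitted model, observed climatology and
#'   grid used to build the bin-0 (observed era) fields.
#' @param season_map named list mapping season names to calendar months;
#'   must partition 1:12.
#' @param bin_width years per bin (10 or 20 in practice).
#' @param mode `"mean-then-classify"` (classify the seasonal mean
#'   probability field at the cut-point, then count) or
#'   `"classify-then-mean"` (average monthly occupancy indicators).
#' @return a `seasonal_summary`: list with `table` (tibble `season`, `bin`,
#'   `occupied_fraction`) and `fields` (per season-bin mean probability).
#' @export
seasonal_decadal_summary <- function(projection, fit, climatology, grid,
                                     season_map = bt_season_map(),
                                     bin_width = 10,
                                     mode = c("mean-then-classify",
                                              "classify-then-mean")) {
  mode <- match.arg(mode)
  months_used <- sort(unlist(season_map))
  assert_that(identical(as.integer(months_used), 1:12),
              "season_map must partition months 1..12")
  H <- projection$horizon
  n_bins <- floor(H / bin_width)
  assert_that(n_bins >= 1, "horizon shorter than one bin")
  shelf <- attr(projection, "shelf_mask")
  cpt <- projection$cutpoint
  # bin 0: observed-era prediction from the climatology
  prob0 <- matrix(NA_real_, nrow(grid), 12)
  prob0[shelf, ] <- predict_probability(
    fit, climatology[shelf, ], matrix(grid$depth[shelf], sum(shelf), 12))
  rows <- list(); fields <- list()
  for (sn in names(season_map)) {
    mo <- season_map[[sn]]
    for (b in 0:n_bins) {
      if (b == 0) {
        pf <- rowMeans(prob0[, mo, drop = FALSE])
        of <- if (mode == "mean-then-classify")
          mean(classify_occupancy(pf, cpt)[shelf]) else
          mean(classify_occupancy(prob0[, mo, drop = FALSE], cpt)[shelf, ])
      } else {
        yrs <- ((b - 1) * bin_width + 1):(b * bin_width)
        block <- projection$probability[, mo, yrs, drop = FALSE]
        pf <- rowMeans(matrix(block, nrow = dim(block)[1]))
        of <- if (mode == "mean-then-classify")
          mean(classify_occupancy(pf, cpt)[shelf]) else
          mean(classify_occupancy(block, cpt)[shelf, , ])
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        season = sn, bin = b, occupied_fraction = of)
      fields[[paste(sn, b, sep = ".")]] <- pf
    }
  }
  structure(list(table = do.call(rbind, rows), fields = fields,
                 bin_width = bin_width, cutpoint = cpt, mode = mode),
            class = "seasonal_summary")
}

#' Habitat trend report
#'
#' Long-format table of the occupied shelf fraction by season and year bin,
#' with the change relative to bin 0 (the observed era).
#'
#' @param summary a `seasonal_summary`.
#' @return tibble with `season`, `bin`, `occupied_fraction`,
#'   `change_vs_observed`.
#' @export
habitat_trend_report <- function(summary) {
  tab <- summary$table
  assert_that(length(unique(tab$bin)) >= 2, "need at least two bins")
  base <- tab[tab$bin == 0, c("season", "occupied_fraction")]
  names(base)[2] <- "base_fraction"
  out <- merge(tab, base, by = "season", sort = FALSE)
  out$change_vs_observed <- out$occupied_fraction - out$base_fraction
  out <- out[order(match(out$season, unique(tab$season)), out$bin), ]
  tibble::as_tibble(out[, c("season", "bin", "occupied_fraction",
                            "change_vs_observed")])
}
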