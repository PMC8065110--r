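#' Pipeline configuration
#'
#' Collects every knob of the end-to-end synthetic study in one object so a
#' run is a pure function of its configuration. Defaults reproduce the
#' study conditions: a 10-km shelf grid between 33.5N and 41.6N, a ten-year
#' study period, an 80-year projection with ~3 degC shelf-mean warming
#' graded towards the north, and a planted truth surface peaking at
#' 21.5 degC / 50 m.
#'
#' @param seed master integer seed; every stage draws a sub-seed from it.
#' @param lon_range,lat_range,cell_size grid extent and resolution.
#' @param coast coastline parameters ([coast_line()]).
#' @param bathymetry list passed to [make_bathymetry()] (`slope`,
#'   `noise_sd`).
#' @param lat_band,max_depth study mask ([apply_study_mask()]).
#' @param climatology list passed to [make_sst_climatology()].
#' @param deltas list passed to [make_deltas()] (`end_warming`,
#'   `north_south_gradient`); the horizon is taken from `horizon`.
#' @param truth a [truth_surface()].
#' @param occurrence_source `"truth"` for direct Bernoulli draws from the
#'   planted surface, `"tracks"` to route presence through simulated
#'   telemetry, the speed filter, the CTCRW smoother and gridding.
#' @param n_years study years of occupancy draws.
#' @param months calendar months in the study period.
#' @param tracks list passed to [simulate_tracks()] when
#'   `occurrence_source = "tracks"`.
#' @param vmax speed-filter bound (km/h).
#' @param terms candidate model terms for [forward_stepwise()].
#' @param cutpoint optional fixed cut-point overriding the IU selection.
#' @param horizon projection horizon in years.
#' @param bin_width years per summary bin (10 or 20).
#' @param fraction_mode see [seasonal_decadal_summary()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            lon_range = c(-77, -65), lat_range = c(33, 42),
                            cell_size = 10000, coast = coast_line(),
                            bathymetry = list(slope = list(rate = 4, max_depth = 320,
                                                           widen_north = 2.5),
                                              noise_sd = 0),
                            lat_band = c(33.5, 41.6), max_depth = 200,
                            climatology = list(), deltas = list(),
                            truth = default_truth_surface(),
                            occurrence_source = c("truth", "tracks"),
                            n_years = 10, months = 1:12,
                            tracks = list(n_animals = 8),
                            vmax = 5,
                            terms = c("sst", "sst2", "depth", "depth2"),
                            cutpoint = NULL, horizon = 80, bin_width = 10,
                            fraction_mode = "mean-then-classify") {
  cfg <- list(seed = as.integer(seed), lon_range = lon_range,
              lat_range = lat_range, cell_size = cell_size, coast = coast,
              bathymetry = bathymetry, lat_band = lat_band,
              max_depth = max_depth, climatology = climatology,
              deltas = deltas, truth = truth,
              occurrence_source = match.arg(occurrence_source),
              n_years = n_years, months = months, tracks = tracks,
              vmax = vmax, terms = terms, cutpoint = cutpoint,
              horizon = horizon, bin_width = bin_width,
              fraction_mode = fraction_mode)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic habitat pipeline
#'
#' Executes the stages in order -- environment simulation, (optionally)
#' track simulation and processing, gridding, model fitting and selection,
#' ROC / Index-of-Union classification, climate-delta projection and
#' seasonal trend summary -- and returns every intermediate artifact.
#' Identical configurations give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the occurrence table,
#'   selected coefficients, selection trace, ROC summary and trend report
#'   are written there as CSV together with the resolved configuration.
#' @return a `pipeline_result` list: `grid`, `climatology`, `deltas`,
#'   `tracks` (when used), `occurrence`, `selection` (fit + trace), `roc`,
#'   `cutpoint`, `projection`, `summary`, `trend`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  subseed <- function(k) derive_seed(config$seed, k)
  grid <- make_grid(config$lon_range, config$lat_range, config$cell_size,
                    coast = config$coast)
  grid <- do.call(make_bathymetry,
                  c(list(grid = grid), config$bathymetry, list(seed = subseed(1))))
  grid <- apply_study_mask(grid, config$lat_band, config$max_depth)
  clim <- do.call(make_sst_climatology,
                  c(list(grid = grid), config$climatology, list(seed = subseed(2))))
  deltas <- do.call(make_deltas,
                    c(list(grid = grid, horizon_years = config$horizon),
                      config$deltas))
  tracks <- NULL
  if (config$occurrence_source == "tracks") {
    tracks <- do.call(simulate_tracks,
                      c(config$tracks, list(seed = subseed(3))))
    daily <- do.call(rbind, lapply(tracks, function(tr) {
      ft <- process_track(tr, vmax = config$vmax)
      tibble::tibble(animal_id = attr(ft, "animal_id"), date = ft$date,
                     x = ft$x, y = ft$y)
    }))
    pres <- assign_cells(daily, grid)
    occurrence <- build_occurrence_table(
      pres, grid, clim, study_years = sort(unique(pres$year)),
      months = config$months)
  } else {
    occurrence <- simulate_occupancy(config$truth, grid, clim,
                                     months = config$months,
                                     n_years = config$n_years, seed = subseed(4))
  }
  selection <- forward_stepwise(occurrence, candidate_terms = config$terms)
  fit <- selection$fit
  probs <- predict_probability(fit, occurrence$sst_c, occurrence$depth_m)
  roc <- roc_curve(probs, occurrence$y)
  cut <- if (is.null(config$cutpoint)) iu_cutpoint(roc) else
    structure(list(c = config$cutpoint, iu_value = NA_real_,
                   se_at_c = NA_real_, sp_at_c = NA_real_, auc = roc$auc),
              class = "cutpoint_result")
  projection <- project_occupancy(fit, clim, deltas, grid, cut$c,
                                  horizon = config$horizon)
  summary <- seasonal_decadal_summary(projection, fit, clim, grid,
                                      bin_width = config$bin_width,
                                      mode = config$fraction_mode)
  trend <- habitat_trend_report(summary)
  res <- structure(list(grid = grid, climatology = clim, deltas = deltas,
                        tracks = tracks, occurrence = occurrence,
                        selection = selection, fit = fit, roc = roc,
                        cutpoint = cut, projection = projection,
                        summary = summary, trend = trend, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$occurrence, file.path(out_dir, "occurrence_table.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(term = names(res$fit$beta),
                              estimate = unname(res$fit$beta)),
                   file.path(out_dir, "coefficients.csv"), row.names = FALSE)
  utils::write.csv(res$selection$trace, file.path(out_dir, "selection_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(auc = res$roc$auc, c = res$cutpoint$c,
                              se = res$cutpoint$se_at_c,
                              sp = res$cutpoint$sp_at_c),
                   file.path(out_dir, "cutpoint.csv"), row.names = FALSE)
  utils::write.csv(res$trend, file.path(out_dir, "trend_report.csv"),
                   row.names = FALSE)
  writeLines(deparse(unclass(res$config)),
             file.path(out_dir, "config_resolved.txt"))
  invisible(res)
}

#' Satellite-tag deployment summary table
#'
#' The published per-year deployment summary for the 2009-2018 loggerhead
#' tagging programme in the Middle Atlantic Bight: tags deployed per year
#' with mean and standard deviation of curved carapace length (CCL, cm).
#' Used as the input to [cohort_summary()].
#'
#' @return tibble with columns `year`, `count`, `mean_size`, `sd_size`.
#' @export
loggerhead_deployments <- function() {
  tibble::tibble(
    year = 2009:2018,
    count = c(2L, 14L, 26L, 30L, 16L, 18L, 10L, 21L, 24L, 35L),
    mean_size = c(71.8, 77.8, 79.1, 81.9, 79.2, 78.2, 78.7, 80.4, 78.5, 82.7),
    sd_size = c(7.4, 9.2, 7.8, 8.7, 13.4, 9.8, 12.4, 8.6, 12.0, 8.4))
}

#' Pooled cohort statistics from per-year deployment summaries
#'
#' Recovers whole-cohort statistics from per-year (count, mean, sd) rows:
#' the total and mean yearly deployment counts, the count-weighted pooled
#' mean size, and the pooled standard deviation via the exact
#' within-plus-between sum-of-squares decomposition with an overall n - 1
#' denominator.
#'
#' @param deployments data frame with columns `year`, `count`, `mean_size`,
#'   `sd_size` (sd may be NA only where `count == 1`).
#' @return list with `total_count`, `mean_count_per_year`, `pooled_mean`,
#'   `pooled_sd`, `n_years`, and the input as `per_year`.
#' @export
cohort_summary <- function(deployments = loggerhead_deployments()) {
  d <- deployments
  assert_that(all(c("year", "count", "mean_size", "sd_size") %in% names(d)),
              "deployments needs year, count, mean_size, sd_size")
  assert_that(all(d$count >= 1), "each listed year needs count >= 1")
  if (any(is.na(d$sd_size) & d$count > 1))
    stop_bt("sd_size missing for a year with count > 1")
  n <- sum(d$count)
  pooled_mean <- sum(d$count * d$mean_size) / n
  sd0 <- ifelse(is.na(d$sd_size), 0, d$sd_size)
  ss_within <- sum((d$count - 1) * sd0^2)
  ss_between <- sum(d$count * (d$mean_size - pooled_mean)^2)
  pooled_sd <- if (n > 1) sqrt((ss_within + ss_between) / (n - 1)) else NA_real_
  list(total_count = n, mean_count_per_year = n / nrow(d),
       pooled_mean = pooled_mean, pooled_sd = pooled_sd,
       n_years = nrow(d), per_year = d)
}
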