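# Run configuration and the two estimation pipelines (train on one record
# set, estimate at arbitrary space-time targets).

#' Run configuration with the reference defaults
#'
#' All defaults equal the reference analysis settings: detrending radii
#' 100,000 m and 2 yr (the projected domain uses the spatial radius only);
#' empirical-covariance maximum ranges 50 km and 5 yr with 5 km spatial bins
#' (yearly temporal bins); kriging with N = 50 neighbours, a 10 km spatial
#' and 2 yr temporal search range; the origin-anchored velocity collapse (see
#' [representative_velocity()]) and the literal projection mode.
#'
#' @param detrend_spatial_radius Metres.
#' @param detrend_temporal_radius Years (space-time domain only).
#' @param cov_spatial_bin_width Metres.
#' @param cov_max_spatial Metres.
#' @param cov_max_temporal Years.
#' @param kriging A [kriging_config()].
#' @param velocity_strategy Passed to [representative_velocity()].
#' @param projection_mode `"literal"` or `"vector"`.
#' @param projection_direction Unit vector, used in `"vector"` mode.
#' @return A list of class `stp_options`.
#' @export
stp_options <- function(detrend_spatial_radius = 100000,
                        detrend_temporal_radius = 2,
                        cov_spatial_bin_width = 5000,
                        cov_max_spatial = 50000,
                        cov_max_temporal = 5,
                        kriging = kriging_config(),
                        velocity_strategy = "origin_mean",
                        projection_mode = c("literal", "vector"),
                        projection_direction = c(1, 1) / sqrt(2)) {
  projection_mode <- match.arg(projection_mode)
  structure(list(
    detrend_spatial_radius = detrend_spatial_radius,
    detrend_temporal_radius = detrend_temporal_radius,
    cov_spatial_bin_width = cov_spatial_bin_width,
    cov_max_spatial = cov_max_spatial,
    cov_max_temporal = cov_max_temporal,
    kriging = kriging,
    velocity_strategy = velocity_strategy,
    projection_mode = projection_mode,
    projection_direction = projection_direction), class = "stp_options")
}

#' Fit the space-time covariance stage (STP step i)
#'
#' Log-transforms (if needed), detrends with the space-time moving window,
#' computes the empirical space-time covariance of the residuals and fits the
#' separable model.
#'
#' @param records Incidence records.
#' @param opts A [stp_options()].
#' @return List: `records` (with `log_value`, `trend`, `residual`), `grid`
#'   ([empirical_covariance()]), `fit` ([fit_cov_model()]).
#' @export
fit_spacetime_model <- function(records, opts = stp_options()) {
  if (is.null(records$log_value)) records$log_value <- log_transform(records$incidence)
  det <- detrend(records, opts$detrend_spatial_radius, opts$detrend_temporal_radius)
  grid <- empirical_covariance(det,
                               spatial_bin_width = opts$cov_spatial_bin_width,
                               max_spatial = opts$cov_max_spatial,
                               temporal = TRUE,
                               max_temporal = opts$cov_max_temporal)
  fit <- fit_cov_model(grid, "separable_gaussian_exponential")
  list(records = det, grid = grid, fit = fit)
}

#' Fit a naive spatial covariance, ignoring time
#'
#' Pools all records as if they were purely spatial observations at their
#' original coordinates (no projection), detrends with the spatial window
#' only and fits the exponential model. Used as the comparison point for the
#' correlation-lengthening property of the projection.
#'
#' @inheritParams fit_spacetime_model
#' @return List: `records`, `grid`, `fit`.
#' @export
fit_naive_spatial_model <- function(records, opts = stp_options()) {
  if (is.null(records$log_value)) records$log_value <- log_transform(records$incidence)
  det <- detrend(records, opts$detrend_spatial_radius, Inf)
  grid <- empirical_covariance(det,
                               spatial_bin_width = opts$cov_spatial_bin_width,
                               max_spatial = opts$cov_max_spatial,
                               temporal = FALSE)
  fit <- fit_cov_model(grid, "projected_exponential")
  list(records = det, grid = grid, fit = fit)
}

#' Fit the projected-domain covariance stage (STP steps ii-iv)
#'
#' Estimates the representative spread velocity from a fitted space-time
#' stage, projects the record coordinates into the traveling domain, detrends
#' there with the spatial window only, and fits the exponential covariance of
#' the projected lag.
#'
#' @param records Incidence records (with `log_value`, or `incidence`).
#' @param st Result of [fit_spacetime_model()] on the same records.
#' @param opts A [stp_options()].
#' @param t0 Reference year (default: earliest year in `records`).
#' @return List: `velocity` ([representative_velocity()] result with the
#'   projection mode filled in), `t0`, `records` (projected + detrended),
#'   `grid`, `fit`.
#' @export
fit_projected_model <- function(records, st, opts = stp_options(),
                                t0 = min(records$year)) {
  vel <- representative_velocity(st$grid, st$fit$model, opts$velocity_strategy)
  vel$mode <- opts$projection_mode
  if (is.null(records$log_value)) records$log_value <- log_transform(records$incidence)
  proj <- project_coordinates(records, vel, t0,
                              mode = opts$projection_mode,
                              direction = opts$projection_direction)
  if (is.null(proj$town_id)) proj$town_id <- as.character(seq_len(nrow(proj)))
  pr <- data.frame(town_id = proj$town_id, x_m = proj$s_hat_1,
                   y_m = proj$s_hat_2, year = proj$year,
                   log_value = proj$log_value, stringsAsFactors = FALSE)
  det <- detrend(pr, opts$detrend_spatial_radius, Inf)
  grid <- empirical_covariance(det,
                               spatial_bin_width = opts$cov_spatial_bin_width,
                               max_spatial = opts$cov_max_spatial,
                               temporal = FALSE)
  fit <- fit_cov_model(grid, "projected_exponential")
  list(velocity = vel, t0 = t0, records = det, grid = grid, fit = fit)
}

#' One-call STP model fit
#'
#' Chains [fit_spacetime_model()] and [fit_projected_model()] on the full
#' record set.
#'
#' @inheritParams fit_spacetime_model
#' @param t0 Reference year for the projection.
#' @return List with `spacetime` and `projected` stage results.
#' @export
stp_fit <- function(records, opts = stp_options(), t0 = min(records$year)) {
  st <- fit_spacetime_model(records, opts)
  pr <- fit_projected_model(st$records, st, opts, t0)
  list(spacetime = st, projected = pr)
}

# Estimate held-out space-time targets with the STOK pipeline trained on
# `train`; returns log-scale and incidence-scale estimates.
estimate_stok <- function(train, targets, opts = stp_options()) {
  st <- fit_spacetime_model(train, opts)
  kr <- stok_krige(targets, st$records, st$fit$model, opts$kriging)
  tr <- trend_at(targets, st$records, opts$detrend_spatial_radius,
                 opts$detrend_temporal_radius)
  log_est <- kr$value + tr
  list(log_est = log_est, incidence = inverse_log_transform(log_est),
       kriging = kr, fit = st$fit)
}

# Estimate held-out space-time targets with the STP pipeline trained on
# `train`. t0 should be fixed from the full data set for reproducibility.
estimate_stp <- function(train, targets, opts = stp_options(),
                         t0 = min(train$year)) {
  st <- fit_spacetime_model(train, opts)
  pr <- fit_projected_model(st$records, st, opts, t0)
  ptarg <- project_coordinates(targets, pr$velocity, t0,
                               mode = opts$projection_mode,
                               direction = opts$projection_direction)
  ptarg_df <- data.frame(s_hat_1 = ptarg$s_hat_1, s_hat_2 = ptarg$s_hat_2)
  kr <- stp_krige(ptarg_df, pr$records, pr$fit$model, opts$kriging)
  tr <- trend_at(data.frame(x_m = ptarg$s_hat_1, y_m = ptarg$s_hat_2),
                 pr$records, opts$detrend_spatial_radius, Inf)
  log_est <- kr$value + tr
  est <- backtransform_estimates(
    targets,
    data.frame(log_est = log_est,
               incidence_est = inverse_log_transform(log_est),
               variance_est = kr$variance))
  list(log_est = log_est, incidence = est$incidence_est, kriging = kr,
       velocity = pr$velocity, fit = pr$fit, targets = est)
}
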