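# STP core: the spread-velocity quadratic, projected lags, the coordinate
# transform s_hat = s - v*t and its inverse.

#' Solve the spread-velocity quadratic
#'
#' For a separable Gaussian-in-space covariance, equating the space-time model
#' with its traveling-field form \eqn{c(r - v\tau, 0)} yields the quadratic
#' \deqn{\alpha_t \tau v^2 - 2 \alpha_t |h| v - \alpha_s^2 = 0.}
#' The admissible root — the one keeping the projected lag
#' \eqn{\hat r = |h| - v\tau} positive — is
#' \deqn{v = |h|/\tau - (\alpha_s/\tau) \sqrt{|h|^2/\alpha_s^2 + \tau/\alpha_t},}
#' which is always negative. Its magnitude is read as the speed at which the
#' incidence pattern travels; larger \eqn{|v|} means stronger composite
#' space-time correlation along the lag direction.
#'
#' @param h Spatial lag(s) in metres, `>= 0` (vectorised).
#' @param tau Temporal lag(s) in years, strictly positive (the quadratic is
#'   singular at `tau = 0`).
#' @param model A [sep_cov_model()].
#' @return Signed speed(s) in metres/year.
#' @seealso [projected_lag()], [velocity_surface()]
#' @export
#' @examples
#' m <- sep_cov_model(1, 10000, 2)
#' solve_velocity(0, 2, m)      # -5000 m/yr
#' solve_velocity(10000, 2, m)  # 5000 - 5000*sqrt(2) m/yr
solve_velocity <- function(h, tau, model) {
  stopifnot(inherits(model, "sep_cov_model"), all(h >= 0))
  if (any(tau <= 0)) {
    stop("solve_velocity: tau must be > 0; the velocity quadratic is singular at tau = 0")
  }
  h / tau - (model$alpha_s / tau) *
    sqrt(h^2 / model$alpha_s^2 + tau / model$alpha_t)
}

#' Projected (traveling-domain) lag
#'
#' The effective spatial lag in the reduced domain,
#' \eqn{\hat r = |h| - v\tau = \alpha_s \sqrt{|h|^2/\alpha_s^2 + \tau/\alpha_t}},
#' strictly positive for `tau > 0` and equal to `|h|` at `tau = 0`.
#'
#' @inheritParams solve_velocity
#' @param tau Temporal lag(s) in years, `>= 0`.
#' @return Projected lag(s) in metres.
#' @export
projected_lag <- function(h, tau, model) {
  stopifnot(inherits(model, "sep_cov_model"), all(h >= 0), all(tau >= 0))
  model$alpha_s * sqrt(h^2 / model$alpha_s^2 + tau / model$alpha_t)
}

#' Tabulate the spread-velocity surface v(|h|, tau)
#'
#' Evaluates [solve_velocity()] on the Cartesian product of the supplied lag
#' grids, the computable analogue of a velocity-surface plot.
#'
#' @param model A [sep_cov_model()].
#' @param h_grid Spatial lags in metres (`>= 0`).
#' @param tau_grid Temporal lags in years (all `> 0`).
#' @return A data frame with columns `h_m`, `tau_yr`, `speed_m_per_yr`.
#' @export
velocity_surface <- function(model, h_grid = seq(0, 50000, by = 5000),
                             tau_grid = 1:5) {
  stopifnot(all(tau_grid > 0))
  g <- expand.grid(h_m = h_grid, tau_yr = tau_grid,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$speed_m_per_yr <- solve_velocity(g$h_m, g$tau_yr, model)
  g
}

#' Collapse the pairwise velocity surface to one projection speed
#'
#' The coordinate transform needs a single representative speed, but the
#' velocity solver gives one value per (|h|, tau) lag pair. Strategies:
#' `"origin_mean"` (default) evaluates the solver only at the bins with the
#' smallest observed spatial lag (for panel data, the co-located pairs across
#' years) and averages over `tau > 0` weighted by pair counts — the
#' frozen-field (Taylor-hypothesis) inversion of the temporal covariance
#' margin, since under rigid travel the decay of \eqn{c(0, \tau)} is purely
#' advective; `"paircount_mean"` averages over every non-empty bin with
#' `tau > 0` weighted by pair counts (the speed surface decays like
#' \eqn{1/|h|}, so this estimate is pulled toward zero by the distant bins
#' that hold most pairs); `"median"` takes the unweighted median over all
#' `tau > 0` bins; `"fixed:<value>"` bypasses estimation (e.g. `"fixed:0"`).
#' The strategy used is recorded in the result for provenance.
#'
#' @param grid A space-time [empirical_covariance()] grid (`lag_bin_grid` with
#'   a `t_lag` column).
#' @param model A fitted [sep_cov_model()].
#' @param strategy Character, see Details.
#' @return An object of class `velocity_result` with fields `speed`
#'   (m/yr, signed), `strategy`, `mode` (projection mode placeholder, set by
#'   the caller), and `source_lags` (data frame of the bins used with their
#'   speeds and weights).
#' @export
representative_velocity <- function(grid, model, strategy = "origin_mean") {
  stopifnot(inherits(grid, "lag_bin_grid"))
  if (startsWith(strategy, "fixed:")) {
    speed <- as.numeric(sub("^fixed:", "", strategy))
    if (!is.finite(speed)) stop("representative_velocity: unparseable fixed speed in ", strategy)
    return(new_velocity_result(speed, strategy, source_lags = NULL))
  }
  if (is.null(grid$t_lag)) {
    stop("representative_velocity: grid has no temporal lags; need a space-time grid")
  }
  use <- grid$n_pairs > 0 & grid$t_lag > 0
  if (!any(use)) stop("representative_velocity: no non-empty bins with tau > 0")
  src <- grid[use, c("h_mid", "t_lag", "n_pairs")]
  if (strategy == "origin_mean") src <- src[src$h_mid == min(src$h_mid), ]
  src$speed <- solve_velocity(src$h_mid, src$t_lag, model)
  speed <- switch(strategy,
    origin_mean = ,
    paircount_mean = sum(src$speed * src$n_pairs) / sum(src$n_pairs),
    median = stats::median(src$speed),
    stop("representative_velocity: unknown strategy ", strategy))
  new_velocity_result(speed, strategy, source_lags = src)
}

new_velocity_result <- function(speed, strategy, mode = "literal",
                                source_lags = NULL) {
  structure(list(speed = speed, strategy = strategy, mode = mode,
                 source_lags = source_lags),
            class = "velocity_result")
}

#' @export
print.velocity_result <- function(x, ...) {
  cat(sprintf("Spread velocity: %.2f m/yr (strategy = %s, mode = %s)\n",
              x$speed, x$strategy, x$mode))
  invisible(x)
}

#' Project space-time coordinates into the traveling domain
#'
#' Applies \eqn{\hat s = s - v (t - t_0)}. In `"literal"` mode (the default,
#' matching the printed transform \eqn{(\hat s_1, \hat s_2) =
#' (s_1 - v t, s_2 - v t)}) the signed scalar speed is subtracted from each
#' coordinate, a fixed diagonal displacement. In `"vector"` mode the
#' displacement is `speed * (t - t0) * direction` for a unit direction vector.
#' The transform is affine and exactly invertible; see
#' [backproject_coordinates()].
#'
#' @param points Data frame with columns `x_m`, `y_m`, `year`.
#' @param velocity A [representative_velocity()] result or a single finite
#'   number (m/yr).
#' @param t0 Reference year; conventionally the earliest year in the data.
#' @param mode `"literal"` or `"vector"`; defaults to the mode stored in
#'   `velocity` (itself `"literal"` unless changed).
#' @param direction Unit direction vector, used in `"vector"` mode only.
#' @return `points` with added columns `s_hat_1`, `s_hat_2`.
#' @export
project_coordinates <- function(points, velocity, t0,
                                mode = NULL, direction = c(1, 1) / sqrt(2)) {
  stopifnot(is.data.frame(points),
            all(c("x_m", "y_m", "year") %in% names(points)))
  if (inherits(velocity, "velocity_result")) {
    if (is.null(mode)) mode <- velocity$mode
    speed <- velocity$speed
  } else {
    if (is.null(mode)) mode <- "literal"
    speed <- as.numeric(velocity)
  }
  stopifnot(length(speed) == 1L, is.finite(speed))
  mode <- match.arg(mode, c("literal", "vector"))
  dt <- points$year - t0
  if (mode == "literal") {
    points$s_hat_1 <- points$x_m - speed * dt
    points$s_hat_2 <- points$y_m - speed * dt
  } else {
    if (abs(sqrt(sum(direction^2)) - 1) > 1e-8) {
      stop("project_coordinates: direction must be a unit vector")
    }
    points$s_hat_1 <- points$x_m - speed * dt * direction[1]
    points$s_hat_2 <- points$y_m - speed * dt * direction[2]
  }
  points
}

#' Invert the traveling-domain projection
#'
#' @inheritParams project_coordinates
#' @param points Data frame with `s_hat_1`, `s_hat_2`, `year`.
#' @return `points` with recovered `x_m`, `y_m`.
#' @export
backproject_coordinates <- function(points, velocity, t0,
                                    mode = NULL, direction = c(1, 1) / sqrt(2)) {
  stopifnot(is.data.frame(points),
            all(c("s_hat_1", "s_hat_2", "year") %in% names(points)))
  if (inherits(velocity, "velocity_result")) {
    if (is.null(mode)) mode <- velocity$mode
    speed <- velocity$speed
  } else {
    if (is.null(mode)) mode <- "literal"
    speed <- as.numeric(velocity)
  }
  mode <- match.arg(mode, c("literal", "vector"))
  dt <- points$year - t0
  if (mode == "literal") {
    points$x_m <- points$s_hat_1 + speed * dt
    points$y_m <- points$s_hat_2 + speed * dt
  } else {
    points$x_m <- points$s_hat_1 + speed * dt * direction[1]
    points$y_m <- points$s_hat_2 + speed * dt * direction[2]
  }
  points
}

#' Relabel traveling-domain estimates back onto space-time points
#'
#' Estimation in the projected domain assigns a value to the image
#' \eqn{\hat s} of each requested space-time point; the back-transform is a
#' pure relabeling (no interpolation): the estimate at \eqn{(s, t)} is the
#' estimate at its image.
#'
#' @param targets Data frame of space-time targets, one row per requested
#'   point (any columns).
#' @param estimates Data frame (or vector) of estimates at the projected
#'   images, row-aligned with `targets`.
#' @return `targets` with the estimate columns appended.
#' @export
backtransform_estimates <- function(targets, estimates) {
  est <- as.data.frame(estimates)
  if (nrow(est) != nrow(targets)) {
    stop("backtransform_estimates: estimates are not row-aligned with targets")
  }
  cbind(targets, est)
}
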