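# Traveling (frozen) Gaussian random-field simulator on a township-like
# layout. The latent field satisfies Z(s, t) = Z(s - v*t*u, 0) exactly: it is
# drawn once on the projected coordinates and read off at every (s, t).

#' Simulation configuration for a traveling incidence field
#'
#' Describes the world the simulator draws from: a township-like layout of
#' `n_locations` points observed at yearly slices, a zero-mean Gaussian latent
#' field advected rigidly at `velocity_speed` along `velocity_direction`, a
#' smooth planar trend in log-incidence units, and the
#' `exp(y) - 1` back-transform to the incidence scale (clamped at 0, which
#' produces the zero-incidence records seen in real registry data).
#'
#' Defaults emulate a 200-township registry observed over five years on a
#' ~130 km square (the area of the study region the package was built
#' around). The default travel speed of -5000 m/yr along the SW-NE diagonal is
#' the speed the velocity solver returns at lag (|h| = 0, tau = 2 yr) under
#' the reference separable model; the solver's admissible root is always
#' negative, so a negative default keeps the literal projection mode able to
#' align with the simulated travel.
#'
#' @param n_locations Number of locations (>= 2).
#' @param years Integer time slices.
#' @param extent Named numeric `c(xmin, xmax, ymin, ymax)` in metres, positive
#'   area.
#' @param velocity_speed Signed speed in m/yr.
#' @param velocity_direction Unit direction vector of travel.
#' @param cov_family `"exponential"` or `"gaussian"` latent covariance (both
#'   with the practical-range factor 3).
#' @param sill Latent-field variance.
#' @param range_m Practical range of the latent covariance, metres.
#' @param trend_amplitude Amplitude of the planar trend, log-incidence units.
#' @param trend_direction Unit vector of increasing trend (default SW->NE).
#' @param mean_log Baseline mean of the log-incidence field.
#' @param min_separation Minimum distance between layout points, metres.
#' @param jitter_rel Relative diagonal jitter added to the latent covariance
#'   matrix for numerical positive-definiteness.
#' @param seed Integer seed; the same config reproduces the field bit-for-bit.
#' @return An object of class `sim_config`.
#' @seealso [simulate_traveling_field()]
#' @export
sim_config <- function(n_locations = 200L,
                       years = 2008:2012,
                       extent = c(xmin = 0, xmax = 130000, ymin = 0, ymax = 130000),
                       velocity_speed = -5000,
                       velocity_direction = c(1, 1) / sqrt(2),
                       cov_family = c("exponential", "gaussian"),
                       sill = 1,
                       range_m = 15000,
                       trend_amplitude = 1,
                       trend_direction = c(1, 1) / sqrt(2),
                       mean_log = 3,
                       min_separation = 500,
                       jitter_rel = 1e-10,
                       seed = 1L) {
  cov_family <- match.arg(cov_family)
  extent <- check_extent(extent)
  stopifnot(n_locations >= 2, length(years) >= 1, !anyDuplicated(years),
            sill > 0, range_m > 0, min_separation >= 0, trend_amplitude >= 0)
  if (abs(sqrt(sum(velocity_direction^2)) - 1) > 1e-8) {
    stop("sim_config: velocity_direction must have unit norm")
  }
  if (abs(sqrt(sum(trend_direction^2)) - 1) > 1e-8) {
    stop("sim_config: trend_direction must have unit norm")
  }
  structure(list(
    n_locations = as.integer(n_locations), years = sort(as.integer(years)),
    extent = extent, velocity_speed = velocity_speed,
    velocity_direction = velocity_direction, cov_family = cov_family,
    sill = sill, range_m = range_m, trend_amplitude = trend_amplitude,
    trend_direction = trend_direction, mean_log = mean_log,
    min_separation = min_separation, jitter_rel = jitter_rel,
    seed = as.integer(seed)), class = "sim_config")
}

check_extent <- function(extent) {
  if (length(extent) != 4L) stop("extent must be c(xmin, xmax, ymin, ymax)")
  if (is.null(names(extent)) || !all(c("xmin", "xmax", "ymin", "ymax") %in% names(extent))) {
    names(extent) <- c("xmin", "xmax", "ymin", "ymax")
  }
  if (extent["xmax"] <= extent["xmin"] || extent["ymax"] <= extent["ymin"]) {
    stop("extent must have positive area")
  }
  extent
}

# Places points under the current RNG state; shared by generate_layout() and
# simulate_traveling_field() so each keeps a single seeded stream.
place_points <- function(n, extent, min_separation) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n
  while (placed < n) {
    if (attempts >= max_attempts) {
      stop(sprintf(paste0(
        "layout generation failed: could not place %d points with minimum ",
        "separation %g m inside a %g x %g m extent (extent too small for the ",
        "requested separation)"),
        n, min_separation,
        extent["xmax"] - extent["xmin"], extent["ymax"] - extent["ymin"]))
    }
    attempts <- attempts + 1L
    cand <- c(stats::runif(1, extent["xmin"], extent["xmax"]),
              stats::runif(1, extent["ymin"], extent["ymax"]))
    ok <- placed == 0L ||
      min((pts[seq_len(placed), 1] - cand[1])^2 +
          (pts[seq_len(placed), 2] - cand[2])^2) >= min_separation^2
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  colnames(pts) <- c("x_m", "y_m")
  pts
}

#' Generate a township-like point layout
#'
#' Uniform rejection sampling inside a rectangle with a minimum-separation
#' constraint, emulating geometric centres of administrative units.
#'
#' @param n Number of points (>= 2).
#' @param extent Rectangle `c(xmin, xmax, ymin, ymax)` in metres.
#' @param seed Integer seed; identical calls reproduce identical coordinates.
#' @param min_separation Minimum pairwise distance in metres (default 500).
#' @return An `n` x 2 matrix with columns `x_m`, `y_m`.
#' @export
generate_layout <- function(n, extent = c(xmin = 0, xmax = 100000,
                                          ymin = 0, ymax = 100000),
                            seed = 1L, min_separation = 500) {
  if (n < 2) stop("generate_layout: n must be >= 2")
  extent <- check_extent(extent)
  set.seed(seed)
  place_points(as.integer(n), extent, min_separation)
}

latent_cov <- function(d, family, sill, range_m) {
  switch(family,
         gaussian = sill * exp(-3 * d^2 / range_m^2),
         exponential = sill * exp(-3 * d / range_m),
         stop("unknown covariance family ", family))
}

#' Simulate a traveling incidence field
#'
#' Draws a zero-mean Gaussian field once on the projected coordinates
#' \eqn{\hat s = s - v t u} (exact simulation via the symmetric square root of
#' the dense covariance matrix over all distinct projected points) and reads
#' it off at every (location, year), so the frozen-field identity
#' \eqn{Z(s, t) = Z(s - v t u, 0)} holds exactly in the latent values. A
#' planar trend and the baseline are added on the log scale and the field is
#' mapped to incidence per 100,000 by `exp(y) - 1`, clamped at 0.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_field`: a list with `records` (data frame:
#'   `town_id`, `x_m`, `y_m`, `year`, `incidence`, plus the simulation truth
#'   columns `latent`, `trend_true`, `log_true`, `s_hat_1`, `s_hat_2`) and
#'   `config`.
#' @export
simulate_traveling_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pts <- place_points(config$n_locations, config$extent, config$min_separation)
  years <- config$years
  n <- config$n_locations
  recs <- data.frame(
    town_id = rep(sprintf("T%03d", seq_len(n)), times = length(years)),
    x_m = rep(pts[, 1], times = length(years)),
    y_m = rep(pts[, 2], times = length(years)),
    year = rep(years, each = n),
    stringsAsFactors = FALSE)
  trel <- recs$year - min(years)
  u <- config$velocity_direction
  recs$s_hat_1 <- recs$x_m - config$velocity_speed * trel * u[1]
  recs$s_hat_2 <- recs$y_m - config$velocity_speed * trel * u[2]

  # draw once per distinct projected point so co-projected records share the
  # exact same latent value (frozen-field identity is exact, not approximate)
  key <- paste(recs$s_hat_1, recs$s_hat_2, sep = "|")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  up <- cbind(recs$s_hat_1[first], recs$s_hat_2[first])
  m <- nrow(up)
  C <- latent_cov(as.matrix(stats::dist(up)), config$cov_family,
                  config$sill, config$range_m)
  diag(C) <- diag(C) + config$jitter_rel * config$sill
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * config$sill) {
    stop("simulate_traveling_field: covariance matrix not positive definite after jitter")
  }
  L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  z_unique <- drop(L %*% stats::rnorm(m))
  recs$latent <- z_unique[idx]

  tu <- config$trend_direction
  proj <- recs$x_m * tu[1] + recs$y_m * tu[2]
  corners <- with(as.list(config$extent), {
    cx <- c(xmin, xmax, xmin, xmax); cy <- c(ymin, ymin, ymax, ymax)
    cx * tu[1] + cy * tu[2]
  })
  span <- max(corners) - min(corners)
  recs$trend_true <- config$trend_amplitude * (proj - min(corners)) / span
  recs$log_true <- config$mean_log + recs$trend_true + recs$latent
  recs$incidence <- pmax(expm1(recs$log_true), 0)

  structure(list(records = recs, config = config, n_projected_points = m),
            class = "sim_field")
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf(paste0(
    "Traveling-field simulation: %d locations x %d years (%d records, ",
    "%d distinct projected points)\n  family = %s, sill = %.3g, range = %.3g m, ",
    "speed = %.3g m/yr, seed = %d\n"),
    x$config$n_locations, length(x$config$years), nrow(x$records),
    x$n_projected_points, x$config$cov_family, x$config$sill,
    x$config$range_m, x$config$velocity_speed, x$config$seed))
  invisible(x)
}

#' Generate an age-structured female population table
#'
#' Allocates a fixed total population per age stratum across locations
#' (every location gets at least one person per stratum; the remainder is
#' multinomial), providing the person-count denominators that indirect age
#' standardization needs.
#'
#' @param n_locations Number of locations.
#' @param strata Character vector of age-band labels (>= 1).
#' @param totals Total population per stratum (recycled if length 1); each
#'   total must be at least `n_locations`.
#' @param seed Integer seed.
#' @return A data frame with `town_id` and one integer column per stratum;
#'   column sums equal `totals`.
#' @export
generate_age_structure <- function(n_locations,
                                   strata = c("0-29", "30-44", "45-59", "60+"),
                                   totals = 20000L * n_locations, seed = 1L) {
  stopifnot(n_locations >= 1, length(strata) >= 1, !anyDuplicated(strata))
  totals <- rep_len(as.integer(round(totals)), length(strata))
  if (any(totals < n_locations)) {
    stop("generate_age_structure: each stratum total must be >= n_locations")
  }
  set.seed(seed)
  out <- data.frame(town_id = sprintf("T%03d", seq_len(n_locations)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(strata)) {
    extra <- drop(stats::rmultinom(1, totals[i] - n_locations,
                                   rep(1 / n_locations, n_locations)))
    out[[strata[i]]] <- 1L + extra
  }
  out
}
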