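# Indirect age standardization, the log(x+1) normalization and its inverse,
# and moving-window spatiotemporal detrending.

#' Indirect age standardization
#'
#' Classic indirect method: expected cases under reference age-specific rates
#' are \eqn{E = \sum_a pop_a \times rate_a / 10^5}; the standardized incidence
#' ratio is \eqn{SIR = observed / E}; the standardized rate is
#' \eqn{SIR \times} the reference overall rate.
#'
#' @param observed_cases Non-negative observed case count.
#' @param population Person counts per age stratum (named or positional;
#'   must align with `reference_rates`).
#' @param reference_rates Reference age-specific rates per 100,000, same
#'   strata as `population`.
#' @param reference_overall_rate Reference overall rate per 100,000.
#' @return Standardized rate per 100,000. Equals `reference_overall_rate`
#'   when `observed_cases` equals the expected count.
#' @export
#' @examples
#' indirect_standardize(60, 100000, 30, 30)  # E = 30, SIR = 2 -> 60
indirect_standardize <- function(observed_cases, population, reference_rates,
                                 reference_overall_rate) {
  stopifnot(length(observed_cases) == 1L, observed_cases >= 0,
            length(population) == length(reference_rates),
            all(population >= 0), all(reference_rates >= 0),
            reference_overall_rate >= 0)
  if (!is.null(names(population)) && !is.null(names(reference_rates)) &&
      !identical(names(population), names(reference_rates))) {
    stop("indirect_standardize: population and reference_rates strata do not match")
  }
  expected <- sum(population * reference_rates) / 1e5
  if (expected == 0) {
    if (observed_cases == 0) {
      warning("indirect_standardize: expected count is 0; returning rate 0")
      return(0)
    }
    stop("indirect_standardize: expected count is 0 but observed cases > 0 (no reference support)")
  }
  observed_cases / expected * reference_overall_rate
}

#' log(x+1) transform and its inverse
#'
#' Incidence rates are left-skewed with exact zeros, so modelling is done on
#' `log(incidence + 1)`. The inverse maps a log-scale estimate back with
#' `exp(y) - 1`, clamped at 0 so negative log-scale estimates yield zero
#' incidence rather than a negative rate. No lognormal bias correction is
#' applied.
#'
#' @param incidence Non-negative rate(s) per 100,000.
#' @return `log_transform`: values `log(incidence + 1)`.
#' @export
log_transform <- function(incidence) {
  if (any(incidence < 0, na.rm = TRUE)) {
    stop("log_transform: negative incidence")
  }
  log1p(incidence)
}

#' @rdname log_transform
#' @param log_value Log-scale value(s).
#' @return `inverse_log_transform`: rates `pmax(exp(log_value) - 1, 0)`.
#' @export
inverse_log_transform <- function(log_value) {
  pmax(expm1(log_value), 0)
}

#' Moving-window spatiotemporal detrending
#'
#' The trend at a record is the unweighted mean of `log_value` over all
#' records (the record itself included) within `spatial_radius` metres and
#' within `temporal_radius` years (inclusive, `|year difference| <= radius`);
#' the residual is `log_value - trend`, so `trend + residual` reconstructs
#' `log_value` exactly. Pass `temporal_radius = Inf` for a purely spatial
#' window (used in the projected domain, where time has been absorbed into
#' the coordinates).
#'
#' @param records Data frame with `x_m`, `y_m`, `log_value` and, if a finite
#'   temporal radius is used, `year`. If `log_value` is absent but
#'   `incidence` is present, `log_value` is computed via [log_transform()].
#' @param spatial_radius Metres (default 100,000).
#' @param temporal_radius Years (default 2); `Inf` disables the temporal
#'   window.
#' @return `records` with `trend` and `residual` columns populated.
#' @export
detrend <- function(records, spatial_radius = 100000, temporal_radius = 2) {
  stopifnot(is.data.frame(records), spatial_radius > 0, temporal_radius > 0)
  if (is.null(records$log_value)) {
    if (is.null(records$incidence)) {
      stop("detrend: records need a log_value (or incidence) column")
    }
    records$log_value <- log_transform(records$incidence)
  }
  W <- as.matrix(stats::dist(records[, c("x_m", "y_m")])) <= spatial_radius
  if (is.finite(temporal_radius)) {
    if (is.null(records$year)) stop("detrend: finite temporal_radius needs a year column")
    W <- W & (abs(outer(records$year, records$year, "-")) <= temporal_radius)
  }
  cnt <- rowSums(W)
  stopifnot(all(cnt >= 1))  # each window contains its own record
  records$trend <- drop(W %*% records$log_value) / cnt
  records$residual <- records$log_value - records$trend
  records
}

#' Evaluate the moving-window trend at arbitrary target points
#'
#' Same estimator as [detrend()] but centred on points that need not be data
#' records (used to add the trend back to kriged residuals). A target whose
#' window is empty falls back to the global mean of `log_value`.
#'
#' @param targets Data frame with `x_m`, `y_m` (and `year` if
#'   `temporal_radius` is finite).
#' @param records Data frame with `x_m`, `y_m`, `log_value` (and `year`).
#' @inheritParams detrend
#' @return Numeric vector of trend values, one per target row.
#' @export
trend_at <- function(targets, records, spatial_radius = 100000,
                     temporal_radius = 2) {
  stopifnot(is.data.frame(targets), is.data.frame(records),
            !is.null(records$log_value))
  dx <- outer(targets$x_m, records$x_m, "-")
  dy <- outer(targets$y_m, records$y_m, "-")
  W <- dx^2 + dy^2 <= spatial_radius^2
  if (is.finite(temporal_radius)) {
    W <- W & (abs(outer(targets$year, records$year, "-")) <= temporal_radius)
  }
  cnt <- rowSums(W)
  tr <- drop(W %*% records$log_value) / pmax(cnt, 1)
  tr[cnt == 0] <- mean(records$log_value)
  tr
}
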