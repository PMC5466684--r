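# Empirical covariance estimation on binned lags (space-time and projected
# domains) and weighted-least-squares model fitting with AIC.

#' Empirical covariance on binned lags
#'
#' Method-of-moments estimator per lag bin,
#' \deqn{\hat C(bin) = \frac{1}{N_{bin}} \sum_{(i,j) \in bin} (z_i - \bar m)(z_j - \bar m),}
#' with \eqn{\bar m} the global mean of the values. Unordered pairs are used
#' (each pair counted once) and self-pairs populate the zero-lag bin, whose
#' estimate is therefore the population variance (1/n convention). Spatial
#' bins are `{0}` exactly, then half-open intervals of width
#' `spatial_bin_width` up to `max_spatial`; with `temporal = TRUE` each
#' spatial bin is crossed with integer year lags `0..max_temporal` (yearly
#' data). Lags beyond the maximum ranges are discarded.
#'
#' @param records Data frame with coordinates `x_m`, `y_m`, the value column,
#'   and `year` when `temporal = TRUE`. Values should be detrended
#'   (approximately zero-mean) residuals.
#' @param value_col Name of the value column (default `"residual"`).
#' @param spatial_bin_width Metres (default 5000).
#' @param max_spatial Maximum spatial lag retained, metres (default 50,000).
#' @param temporal If `TRUE` (default) bin jointly over space and integer
#'   year lags; if `FALSE` estimate a purely spatial covariance (projected
#'   domain).
#' @param max_temporal Maximum absolute year lag retained (default 5).
#' @return A data frame of class `lag_bin_grid` with columns `h_lo`, `h_hi`,
#'   `h_mid` (bin centre; 0 for the zero bin), `t_lag` (only when temporal),
#'   `cov`, `n_pairs`. Bins with no pairs are dropped.
#' @export
empirical_covariance <- function(records, value_col = "residual",
                                 spatial_bin_width = 5000,
                                 max_spatial = 50000,
                                 temporal = TRUE, max_temporal = 5) {
  stopifnot(is.data.frame(records), value_col %in% names(records),
            spatial_bin_width > 0, max_spatial > 0)
  n <- nrow(records)
  if (n < 2) stop("empirical_covariance: need at least 2 records")
  z <- records[[value_col]] - mean(records[[value_col]])
  D <- as.matrix(stats::dist(records[, c("x_m", "y_m")]))
  iu <- upper.tri(D, diag = TRUE)  # diag = self-pairs -> zero-lag variance bin
  h <- D[iu]
  p <- tcrossprod(z)[iu]
  if (temporal) {
    if (is.null(records$year)) stop("empirical_covariance: temporal = TRUE needs a year column")
    tl <- abs(outer(records$year, records$year, "-"))[iu]
  } else {
    tl <- rep(0, length(h))
  }
  keep <- h <= max_spatial & tl <= max_temporal
  h <- h[keep]; tl <- tl[keep]; p <- p[keep]
  sbin <- ifelse(h == 0, 0L, as.integer(ceiling(h / spatial_bin_width)))
  grp <- sbin * (max_temporal + 1L) + as.integer(tl)
  sums <- rowsum(cbind(p, 1), grp)
  gid <- as.integer(rownames(sums))
  out <- data.frame(
    h_lo = ifelse(gid %/% (max_temporal + 1L) == 0L, 0,
                  (gid %/% (max_temporal + 1L) - 1L) * spatial_bin_width),
    h_hi = (gid %/% (max_temporal + 1L)) * spatial_bin_width,
    h_mid = ifelse(gid %/% (max_temporal + 1L) == 0L, 0,
                   (gid %/% (max_temporal + 1L) - 0.5) * spatial_bin_width),
    t_lag = gid %% (max_temporal + 1L),
    cov = sums[, 1] / sums[, 2],
    n_pairs = as.integer(sums[, 2]))
  if (!temporal) out$t_lag <- NULL
  out <- out[order(out$h_mid, if (temporal) out$t_lag else out$h_mid), ]
  rownames(out) <- NULL
  structure(out, class = c("lag_bin_grid", "data.frame"),
            temporal = temporal, spatial_bin_width = spatial_bin_width,
            max_spatial = max_spatial,
            max_temporal = if (temporal) max_temporal else NA)
}

# weighted residual sum of squares of a model against a grid
grid_wrss <- function(pred, grid) {
  sum(grid$n_pairs * (grid$cov - pred)^2)
}

#' Fit a covariance model to an empirical lag grid
#'
#' Pair-count-weighted least squares over the non-empty bins, minimised by a
#' deterministic coarse grid search (17 log-spaced values per parameter)
#' followed by Nelder-Mead refinement started at the grid optimum; there is
#' no randomness, so fits are exactly reproducible. Model selection uses the
#' Gaussian-residual least-squares AIC, \eqn{n \ln(WRSS/n) + 2k}, with `n`
#' the number of non-empty bins and `k` the number of free parameters.
#'
#' Families: `"separable_gaussian_exponential"` fits [sep_cov_model()]
#' (Gaussian in space, exponential in time). Two variants are fitted and the
#' AIC winner kept: the full three-parameter model, and a time-stable
#' two-parameter variant with the temporal factor pinned at 1
#' (`alpha_t = Inf`). A field whose covariance shows no temporal decay over
#' the observed lags therefore gets `alpha_t = Inf`, for which the spread
#' velocity of [solve_velocity()] is exactly zero and the projection
#' degenerates to the identity. On a grid without temporal lags only the
#' time-stable variant is available. `"projected_exponential"` fits
#' [proj_cov_model()] to spatial lags, ignoring any temporal column.
#'
#' @param grid A [empirical_covariance()] result.
#' @param family Model family, see Details.
#' @return A list of class `cov_fit`: `model` (classed model object),
#'   `family`, `aic`, `wrss`, `n_bins`, `k`.
#' @export
fit_cov_model <- function(grid,
                          family = c("separable_gaussian_exponential",
                                     "projected_exponential")) {
  family <- match.arg(family)
  stopifnot(inherits(grid, "lag_bin_grid"))
  grid <- grid[grid$n_pairs > 0, ]
  temporal <- !is.null(grid$t_lag)
  tl <- if (temporal) grid$t_lag else rep(0, nrow(grid))
  h <- grid$h_mid

  cmax <- max(max(grid$cov), 1e-12)
  cgrid <- exp(seq(log(cmax / 8), log(cmax * 8), length.out = 17))
  amax <- max(h, grid$h_hi)
  agrid <- exp(seq(log(max(amax / 200, 1)), log(4 * amax), length.out = 17))
  n_bins <- nrow(grid)

  run_wls <- function(pred_fun, par_grid, k) {
    if (n_bins < k + 1L) {
      stop("fit_cov_model: need at least ", k + 1L, " non-empty bins, have ",
           n_bins)
    }
    obj <- function(logpar) grid_wrss(pred_fun(exp(logpar)), grid)
    scores <- apply(par_grid, 1L, function(p) grid_wrss(pred_fun(p), grid))
    # Nelder-Mead with restarts: a fresh simplex at the previous optimum
    # guards against premature termination on flat ridges
    opt <- stats::optim(log(par_grid[which.min(scores), ]), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    for (restart in 1:5) {
      nxt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12))
      improved <- opt$value - nxt$value
      opt <- nxt
      if (nxt$convergence == 0L &&
          improved <= 1e-10 * max(opt$value, 1e-300)) break
    }
    list(par = unname(exp(opt$par)), wrss = opt$value, k = k,
         aic = n_bins * log(max(opt$value, 1e-300) / n_bins) + 2 * k)
  }

  if (family == "projected_exponential") {
    best <- run_wls(function(par) par[1] * exp(-3 * h / par[2]),
                    as.matrix(expand.grid(cgrid, agrid)), 2L)
    model <- proj_cov_model(c = best$par[1], alpha = best$par[2])
  } else {
    # time-stable variant: temporal factor pinned at 1 (alpha_t = Inf), one
    # fewer parameter; on a grid with temporal lags both variants are fitted
    # and the AIC winner kept, so a field with no temporal decay gets
    # alpha_t = Inf — and hence a spread velocity of exactly zero
    stable <- run_wls(function(par) par[1] * exp(-3 * h^2 / par[2]^2),
                      as.matrix(expand.grid(cgrid, agrid)), 2L)
    best <- stable
    model <- sep_cov_model(c0 = best$par[1], alpha_s = best$par[2],
                           alpha_t = Inf)
    if (temporal && any(tl > 0)) {
      tgrid <- exp(seq(log(0.25), log(8 * max(tl)), length.out = 17))
      free <- run_wls(
        function(par) par[1] * exp(-3 * h^2 / par[2]^2 - 3 * tl / par[3]),
        as.matrix(expand.grid(cgrid, agrid, tgrid)), 3L)
      if (free$aic < stable$aic) {
        best <- free
        model <- sep_cov_model(c0 = best$par[1], alpha_s = best$par[2],
                               alpha_t = best$par[3])
      }
    }
  }
  structure(list(model = model, family = family, aic = best$aic,
                 wrss = best$wrss, n_bins = n_bins, k = best$k),
            class = "cov_fit")
}

#' @export
print.cov_fit <- function(x, ...) {
  cat(sprintf("Covariance fit (%s): AIC = %.2f, WRSS = %.4g over %d bins\n",
              x$family, x$aic, x$wrss, x$n_bins))
  print(x$model)
  invisible(x)
}
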