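# Ordinary kriging engine: shared augmented-system solver plus the two
# front-ends (spatial OK in the projected domain; space-time OK with the
# separable covariance).

#' Kriging search configuration
#'
#' @param max_neighbors Maximum number of data used per target (N, default
#'   50).
#' @param spatial_radius Spatial search radius in metres (default 10,000).
#' @param temporal_radius Temporal search radius in years (default 2; used by
#'   [stok_krige()] only).
#' @param min_neighbors Minimum usable neighbours (default 3). If fewer data
#'   fall inside the search radii they are doubled up to three times before
#'   failing.
#' @param nugget Nugget variance added at zero lag (default 0; the reference
#'   models have none).
#' @return A list of class `kriging_config`.
#' @export
kriging_config <- function(max_neighbors = 50L, spatial_radius = 10000,
                           temporal_radius = 2, min_neighbors = 3L,
                           nugget = 0) {
  stopifnot(max_neighbors >= min_neighbors, min_neighbors >= 1,
            spatial_radius > 0, temporal_radius > 0, nugget >= 0)
  structure(list(max_neighbors = as.integer(max_neighbors),
                 spatial_radius = spatial_radius,
                 temporal_radius = temporal_radius,
                 min_neighbors = as.integer(min_neighbors),
                 nugget = nugget),
            class = "kriging_config")
}

# Solve the ordinary-kriging augmented system
#   [C 1; 1' 0] [lambda; mu] = [c0vec; 1].
# Retries once with a tiny diagonal jitter if the plain solve fails.
ok_solve <- function(C, c0vec, z, sill, ids = seq_along(z)) {
  n <- length(z)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  b <- c(c0vec, 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) {
    A2 <- A
    diag(A2)[seq_len(n)] <- diag(A2)[seq_len(n)] + 1e-10 * sill
    sol <- tryCatch(solve(A2, b), error = function(e) NULL)
    if (is.null(sol)) {
      stop("ok_solve: singular kriging system (data ids: ",
           paste(utils::head(ids, 10), collapse = ", "), ")")
    }
  }
  w <- sol[seq_len(n)]
  mu <- sol[n + 1L]
  list(value = sum(w * z),
       variance = max(sill - sum(w * c0vec) - mu, 0),
       weights = w, mu = mu, n_neighbors_used = n)
}

# Average exact duplicates (identical covariance signatures) before solving;
# keys is a character vector identifying coincident data.
collapse_duplicates <- function(keys, values) {
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  vals <- drop(rowsum(values, idx)) / tabulate(idx)
  list(first = which(first), values = vals)
}

#' Ordinary kriging at one target from an explicit covariance
#'
#' Low-level single-target estimator: neighbours have already been selected;
#' `C` is their covariance matrix and `c0vec` their covariances with the
#' target. Weights sum to one (the ordinary-kriging unbiasedness constraint)
#' and the kriging variance is \eqn{C(0) - \lambda' c_0 - \mu}.
#'
#' @param C Neighbour covariance matrix (n x n).
#' @param c0vec Covariances between target and neighbours (length n).
#' @param z Neighbour data values (length n).
#' @param sill Model covariance at zero lag, C(0) (plus nugget, if any).
#' @return A list of class `kriging_estimate`: `value`, `variance`,
#'   `weights`, `mu`, `n_neighbors_used`.
#' @export
ok_estimate <- function(C, c0vec, z, sill) {
  stopifnot(length(z) >= 1, nrow(C) == length(z), length(c0vec) == length(z))
  structure(ok_solve(C, c0vec, z, sill), class = "kriging_estimate")
}

# Generic neighbourhood kriging over many targets.
#  cov_data:     function(i, j) covariance between data i and data j (vectorised
#                over index vectors, returns matrix via outer semantics)
# Implemented concretely in the two front-ends to keep the inner loop simple.

krige_loop <- function(n_targets, get_neighbors, get_cov, z, sill, config) {
  out <- data.frame(value = numeric(n_targets), variance = numeric(n_targets),
                    n_neighbors_used = integer(n_targets))
  for (i in seq_len(n_targets)) {
    nb <- get_neighbors(i)
    if (!is.null(nb$exact)) {  # target coincides with a datum: exact interpolation
      out$value[i] <- nb$exact
      out$variance[i] <- 0
      out$n_neighbors_used[i] <- 1L
      next
    }
    cv <- get_cov(i, nb$idx)
    est <- ok_solve(cv$C, cv$c0, z[nb$idx], sill, ids = nb$idx)
    out$value[i] <- est$value
    out$variance[i] <- est$variance
    out$n_neighbors_used[i] <- est$n_neighbors_used
  }
  out
}

# Shared neighbour-selection policy: among eligible data ranked by decreasing
# covariance with the target (stable tie-break on data order), keep the top
# max_neighbors; if fewer than min_neighbors are eligible, double the radii up
# to 3 times.
select_neighbors <- function(eligible_at, cov_to_target, config) {
  for (expand in 0:3) {
    f <- 2^expand
    el <- which(eligible_at(f))
    if (length(el) >= config$min_neighbors) {
      cv <- cov_to_target(el)
      ord <- order(-cv, el)
      return(el[ord][seq_len(min(length(el), config$max_neighbors))])
    }
  }
  stop("kriging: fewer than min_neighbors = ", config$min_neighbors,
       " data within the search radius after 3 radius expansions")
}

#' Spatial ordinary kriging in the projected domain (STP step v)
#'
#' Kriges detrended log-scale residuals at projected target points using the
#' exponential covariance of the projected lag. Euclidean metric on
#' \eqn{(\hat s_1, \hat s_2)}; neighbours within `spatial_radius`, ranked by
#' covariance (equivalently by distance), top `max_neighbors` used. Exact
#' duplicates among the data are averaged; a target coinciding with a datum
#' returns that value with zero variance (exact interpolation).
#'
#' @param targets Data frame with projected coordinates `s_hat_1`, `s_hat_2`
#'   (columns `x_m`/`y_m` are accepted as synonyms).
#' @param data Data frame with `s_hat_1`, `s_hat_2` (or `x_m`/`y_m`) and the
#'   value column `residual` (or `value`).
#' @param model A [proj_cov_model()].
#' @param config A [kriging_config()].
#' @return Data frame with `value` (log-scale residual estimate), `variance`,
#'   `n_neighbors_used`, one row per target.
#' @export
stp_krige <- function(targets, data, model, config = kriging_config()) {
  stopifnot(inherits(model, "proj_cov_model"), inherits(config, "kriging_config"))
  tx <- pick_cols(targets, c("s_hat_1", "x_m")); ty <- pick_cols(targets, c("s_hat_2", "y_m"))
  dx <- pick_cols(data, c("s_hat_1", "x_m"));   dy <- pick_cols(data, c("s_hat_2", "y_m"))
  z <- pick_cols(data, c("residual", "value"))

  dup <- collapse_duplicates(paste(dx, dy, sep = "|"), z)
  dx <- dx[dup$first]; dy <- dy[dup$first]; z <- dup$values
  sill <- model$c + config$nugget

  get_neighbors <- function(i) {
    d2 <- (dx - tx[i])^2 + (dy - ty[i])^2
    hit <- which(d2 < 1e-18)
    if (length(hit) == 1L) return(list(exact = z[hit]))
    idx <- select_neighbors(
      eligible_at = function(f) d2 <= (config$spatial_radius * f)^2,
      cov_to_target = function(el) eval_projected(model, sqrt(d2[el])),
      config = config)
    list(idx = idx)
  }
  get_cov <- function(i, idx) {
    pd <- as.matrix(stats::dist(cbind(dx[idx], dy[idx])))
    C <- eval_projected(model, pd)
    diag(C) <- sill
    c0 <- eval_projected(model, sqrt((dx[idx] - tx[i])^2 + (dy[idx] - ty[i])^2))
    list(C = C, c0 = c0)
  }
  krige_loop(length(tx), get_neighbors, get_cov, z, sill, config)
}

#' Spatiotemporal ordinary kriging (STOK baseline)
#'
#' Ordinary kriging directly in the space-time domain: the covariance between
#' two points is the separable model evaluated at their spatial distance and
#' absolute year lag. Eligible neighbours satisfy `|h| <= spatial_radius` and
#' `|tau| <= temporal_radius`; the `max_neighbors` with highest covariance to
#' the target are used (covariance ranking avoids inventing a composite
#' space-time distance).
#'
#' @param targets Data frame with `x_m`, `y_m`, `year`.
#' @param data Data frame with `x_m`, `y_m`, `year` and `residual` (or
#'   `value`).
#' @param model A [sep_cov_model()].
#' @param config A [kriging_config()].
#' @return Data frame with `value`, `variance`, `n_neighbors_used`.
#' @export
stok_krige <- function(targets, data, model, config = kriging_config()) {
  stopifnot(inherits(model, "sep_cov_model"), inherits(config, "kriging_config"),
            all(c("x_m", "y_m", "year") %in% names(targets)),
            all(c("x_m", "y_m", "year") %in% names(data)))
  z <- pick_cols(data, c("residual", "value"))
  dup <- collapse_duplicates(paste(data$x_m, data$y_m, data$year, sep = "|"), z)
  dx <- data$x_m[dup$first]; dy <- data$y_m[dup$first]
  dyr <- data$year[dup$first]; z <- dup$values
  sill <- model$c0 + config$nugget

  get_neighbors <- function(i) {
    d2 <- (dx - targets$x_m[i])^2 + (dy - targets$y_m[i])^2
    tl <- abs(dyr - targets$year[i])
    hit <- which(d2 < 1e-18 & tl == 0)
    if (length(hit) == 1L) return(list(exact = z[hit]))
    idx <- select_neighbors(
      eligible_at = function(f) d2 <= (config$spatial_radius * f)^2 &
        tl <= config$temporal_radius * f,
      cov_to_target = function(el) eval_separable(model, sqrt(d2[el]), tl[el]),
      config = config)
    list(idx = idx)
  }
  get_cov <- function(i, idx) {
    pd <- as.matrix(stats::dist(cbind(dx[idx], dy[idx])))
    ptau <- abs(outer(dyr[idx], dyr[idx], "-"))
    C <- eval_separable(model, pd, ptau)
    diag(C) <- sill
    c0 <- eval_separable(model,
                         sqrt((dx[idx] - targets$x_m[i])^2 + (dy[idx] - targets$y_m[i])^2),
                         abs(dyr[idx] - targets$year[i]))
    list(C = C, c0 = c0)
  }
  krige_loop(nrow(targets), get_neighbors, get_cov, z, sill, config)
}

pick_cols <- function(df, candidates) {
  for (nm in candidates) if (!is.null(df[[nm]])) return(df[[nm]])
  stop("expected one of columns: ", paste(candidates, collapse = ", "))
}
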