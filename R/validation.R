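# k-fold cross-validation protocol and ME/MAE/RMSE error summaries; the
# STP-vs-STOK comparison experiment.

#' Random k-fold assignment
#'
#' Uniform random partition into `k` folds whose sizes differ by at most one;
#' deterministic given the seed.
#'
#' @param n Number of records, or a data frame (its row count is used).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`, length `n`.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  sample(rep_len(seq_len(as.integer(k)), n))
}

#' Cross-validation error summary (ME / MAE / RMSE)
#'
#' Mean error `mean(est - true)`, mean absolute error and root mean square
#' error, computed on whatever scale the inputs are on; the package's
#' cross-validation routines pass fully back-transformed incidence per
#' 100,000.
#'
#' @param true Observed values.
#' @param est Estimated values, same length.
#' @return A list of class `error_summary` with `me`, `mae`, `rmse`, `n`.
#' @export
#' @examples
#' error_summary(c(10, 20, 30), c(12, 18, 33))  # ME 1, MAE 2.33, RMSE 2.38
error_summary <- function(true, est) {
  stopifnot(length(true) == length(est), length(true) >= 1,
            all(is.finite(true)), all(is.finite(est)))
  e <- est - true
  structure(list(me = mean(e), mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
                 n = length(e)), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("ME = %.4f, MAE = %.4f, RMSE = %.4f (n = %d), per 100,000\n",
              x$me, x$mae, x$rmse, x$n))
  invisible(x)
}

#' k-fold cross-validation of the STP or STOK pipeline
#'
#' Runs the full pipeline per fold with no leakage: detrending, covariance
#' fitting and (for STP) velocity estimation are redone inside each training
#' fold; held-out records are estimated and back-transformed to the incidence
#' scale, on which the error summary is computed.
#'
#' @param records Incidence records (`town_id`, `x_m`, `y_m`, `year`,
#'   `incidence`).
#' @param method `"stp"` or `"stok"`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold split.
#' @param opts A [stp_options()] run configuration.
#' @param folds Optional pre-computed fold labels (overrides `k`/`seed`),
#'   used to evaluate both methods on identical folds.
#' @return A list of class `cv_result`: `summary` ([error_summary()]),
#'   `records` (per-record data frame with `true`, `est`, `fold`, `method`),
#'   `method`, and for STP the per-fold velocities.
#' @export
crossvalidate <- function(records, method = c("stp", "stok"), k = 10L,
                          seed = 1L, opts = stp_options(), folds = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records),
            all(c("x_m", "y_m", "year", "incidence") %in% names(records)))
  if (is.null(folds)) folds <- kfold_split(records, k, seed)
  stopifnot(length(folds) == nrow(records))
  if (is.null(records$town_id)) records$town_id <- as.character(seq_len(nrow(records)))
  records$log_value <- log_transform(records$incidence)
  est <- rep(NA_real_, nrow(records))
  velocities <- list()
  for (f in sort(unique(folds))) {
    test_i <- which(folds == f)
    train <- records[-test_i, , drop = FALSE]
    test <- records[test_i, , drop = FALSE]
    if (method == "stok") {
      est[test_i] <- estimate_stok(train, test, opts)$incidence
    } else {
      r <- estimate_stp(train, test, opts, t0 = min(records$year))
      est[test_i] <- r$incidence
      velocities[[as.character(f)]] <- r$velocity$speed
    }
  }
  per <- data.frame(town_id = records$town_id, year = records$year,
                    true = records$incidence, est = est, fold = folds,
                    method = method, stringsAsFactors = FALSE)
  structure(list(summary = error_summary(per$true, per$est), records = per,
                 method = method,
                 fold_velocities = if (length(velocities)) unlist(velocities)),
            class = "cv_result")
}

#' Compare STP and STOK by cross-validation on identical folds
#'
#' @inheritParams crossvalidate
#' @return A list of class `stp_stok_comparison`: `stp` and `stok`
#'   ([crossvalidate()] results) plus the shared `folds`.
#' @export
compare_stp_stok <- function(records, k = 10L, seed = 1L, opts = stp_options()) {
  folds <- kfold_split(records, k, seed)
  stp <- crossvalidate(records, "stp", opts = opts, folds = folds)
  stok <- crossvalidate(records, "stok", opts = opts, folds = folds)
  structure(list(stp = stp, stok = stok, folds = folds),
            class = "stp_stok_comparison")
}

#' @export
print.stp_stok_comparison <- function(x, ...) {
  cat("STP : "); print(x$stp$summary)
  cat("STOK: "); print(x$stok$summary)
  invisible(x)
}
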