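#' Separable space-time covariance model
#'
#' Constructs the multiplicative separable covariance model used for the
#' space-time domain: a Gaussian spatial component times an exponential
#' temporal component,
#' \deqn{c(h, \tau) = c_0 \exp(-3 |h|^2 / \alpha_s^2 - 3 \tau / \alpha_t).}
#' The factor 3 follows the "practical range" convention: the spatial
#' component decays to \eqn{e^{-3} \approx 0.05} at \eqn{|h| = \alpha_s} and
#' the temporal component at \eqn{\tau = \alpha_t}.
#'
#' @param c0 Sill (variance at zero lag), must be positive.
#' @param alpha_s Spatial range in metres, must be positive.
#' @param alpha_t Temporal range in years, must be positive.
#' @return An object of class `sep_cov_model`.
#' @seealso [eval_separable()], [proj_cov_model()], [solve_velocity()]
#' @export
#' @examples
#' m <- sep_cov_model(1, 10000, 2)
#' eval_separable(m, h = 10000, tau = 0)  # e^-3
sep_cov_model <- function(c0, alpha_s, alpha_t) {
  stopifnot(is.numeric(c0), length(c0) == 1L, c0 > 0,
            is.numeric(alpha_s), length(alpha_s) == 1L, alpha_s > 0,
            is.numeric(alpha_t), length(alpha_t) == 1L, alpha_t > 0)
  structure(list(c0 = c0, alpha_s = alpha_s, alpha_t = alpha_t),
            class = "sep_cov_model")
}

#' Projected-domain exponential covariance model
#'
#' Covariance of the traveling (projected) field as a function of the
#' projected lag \eqn{\hat r}:
#' \deqn{c(\hat r) = c \exp(-3 \hat r / \alpha).}
#'
#' @param c Sill, positive.
#' @param alpha Range in metres, positive.
#' @return An object of class `proj_cov_model`.
#' @export
#' @examples
#' eval_projected(proj_cov_model(1, 15000), 15000)  # e^-3
proj_cov_model <- function(c, alpha) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  structure(list(c = c, alpha = alpha), class = "proj_cov_model")
}

#' Evaluate the separable space-time covariance
#'
#' @param model A [sep_cov_model()].
#' @param h Spatial lag(s) in metres, `>= 0` (vectorised).
#' @param tau Temporal lag(s) in years, `>= 0` (vectorised, recycled).
#' @return Covariance value(s) in `(0, c0]`.
#' @export
eval_separable <- function(model, h, tau) {
  stopifnot(inherits(model, "sep_cov_model"), all(h >= 0), all(tau >= 0))
  model$c0 * exp(-3 * h^2 / model$alpha_s^2 - 3 * tau / model$alpha_t)
}

#' Evaluate the projected exponential covariance
#'
#' @param model A [proj_cov_model()].
#' @param r_hat Projected lag(s) in metres, `>= 0`.
#' @return Covariance value(s) in `(0, c]`.
#' @export
eval_projected <- function(model, r_hat) {
  stopifnot(inherits(model, "proj_cov_model"), all(r_hat >= 0))
  model$c * exp(-3 * r_hat / model$alpha)
}

#' @export
print.sep_cov_model <- function(x, ...) {
  cat(sprintf(
    "Separable space-time covariance: c0 = %.4g, alpha_s = %.4g m, alpha_t = %.4g yr\n",
    x$c0, x$alpha_s, x$alpha_t))
  invisible(x)
}

#' @export
print.proj_cov_model <- function(x, ...) {
  cat(sprintf("Projected exponential covariance: c = %.4g, alpha = %.4g m\n",
              x$c, x$alpha))
  invisible(x)
}
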