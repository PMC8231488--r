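#' Gaussian correntropy kernel
#'
#' Evaluates the Gaussian kernel \eqn{G_\sigma(e) = \exp(-e^2 / (2\sigma^2))}
#' used as the correntropy similarity measure between a model prediction and
#' an observation. Residuals near zero receive weight close to 1, while large
#' (outlying) residuals are exponentially down-weighted — this is the
#' mechanism that makes the maximum correntropy criterion robust to
#' heavy-tailed noise.
#'
#' @param e numeric vector of errors/residuals.
#' @param sigma kernel bandwidth, a single positive number. `Inf` is accepted
#'   as a sentinel meaning "no down-weighting": every weight is exactly 1 and
#'   the criterion degenerates to least squares.
#' @return numeric vector of weights in `(0, 1]`.
#' @examples
#' gaussian_kernel(0, 2)           # 1
#' gaussian_kernel(2, 2)           # exp(-1/2)
#' gaussian_kernel(c(-1, 0, 1), Inf)
#' @export
gaussian_kernel <- function(e, sigma) {
  check_bandwidth(sigma)
  if (is.infinite(sigma)) {
    out <- rep(1, length(e))
    attributes(out) <- attributes(as.numeric(e))
    return(out)
  }
  exp(-as.numeric(e)^2 / (2 * sigma^2))
}

#' Influence function of the maximum correntropy estimator
#'
#' \eqn{\varphi(e) = e \exp(-e^2/(2\sigma^2))}, the score of the correntropy
#' cost. It is odd, continuous, and bounded on the whole real line with
#' extrema \eqn{\pm\sigma e^{-1/2}} at \eqn{e = \pm\sigma}; boundedness of the
#' influence function is what makes the filter infinitesimally robust — a
#' single arbitrarily large outlier can shift the estimate by at most a
#' bounded amount, and its pull actually *decreases* once it exceeds the
#' bandwidth.
#'
#' @inheritParams gaussian_kernel
#' @return numeric vector, same length as `e`.
#' @export
influence_phi <- function(e, sigma) {
  as.numeric(e) * gaussian_kernel(e, sigma)
}

#' Asymptotic information-matrix constant of the correntropy estimator
#'
#' For residuals distributed \eqn{N(0, \theta^2)}, the asymptotic information
#' of the maximum correntropy estimator is the least-squares information
#' \eqn{M^\top M} scaled by
#' \deqn{c(\sigma,\theta) =
#'   \frac{(E[\varphi'(e)])^2}{E[\varphi(e)^2]} =
#'   \frac{\sigma^3 (\sigma^2 + 2\theta^2)^{3/2}}{\theta^2 (\sigma^2 + \theta^2)^3}.}
#' The constant is below \eqn{1/\theta^2} for any finite bandwidth
#' (robustness is paid for in asymptotic efficiency) and converges to
#' \eqn{1/\theta^2}, the Gaussian least-squares information, as
#' \eqn{\sigma \to \infty}.
#'
#' @param sigma kernel bandwidth (positive; `Inf` allowed).
#' @param theta standard deviation of the reference residual distribution.
#' @return a positive scalar.
#' @export
mcc_info_constant <- function(sigma, theta) {
  check_bandwidth(sigma)
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) || theta <= 0) {
    stop("`theta` must be a single positive number.", call. = FALSE)
  }
  if (is.infinite(sigma)) return(1 / theta^2)
  sigma^3 * (sigma^2 + 2 * theta^2)^1.5 / (theta^2 * (sigma^2 + theta^2)^3)
}

check_bandwidth <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    stop("kernel bandwidth `sigma` must be a single positive number ",
         "(Inf allowed as the no-weighting sentinel).", call. = FALSE)
  }
  invisible(sigma)
}
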