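#' Whitened augmented regression for one filter update
#'
#' Stacks the prior pseudo-measurement \eqn{\bar{x}_k} and the preprocessed
#' observation \eqn{g(y_k)} into a single regression on the state,
#' \deqn{D_k = M_k x_k + e_k,}
#' whitened so that the stacked noise has identity covariance. `S_chi` and
#' `S_V` are the upper-triangular Cholesky factors with
#' \eqn{S_\chi^\top S_\chi = \bar\chi_k} and \eqn{S_V^\top S_V = V_k}
#' (the information matrices of the prior and of the observation residue);
#' then \eqn{D = [S_\chi \bar x; S_V g(y)]} and \eqn{M = [S_\chi; S_V]}.
#' With this convention \eqn{M^\top M = \bar\chi + V} exactly, so the
#' unweighted normal equations reproduce the information-filter update.
#'
#' @param x_bar prior mean (length-n numeric).
#' @param chi_bar prior information matrix (n x n, symmetric positive definite).
#' @param g_y pseudo-observation (length-n numeric).
#' @param V observation-residue information matrix (n x n, SPD).
#' @return an object of class `augmented_system`: list with `D` (length 2n),
#'   `M` (2n x n), `S_chi`, `S_V`, and `n`.
#' @export
build_augmented_system <- function(x_bar, chi_bar, g_y, V) {
  x_bar <- as.numeric(x_bar)
  g_y <- as.numeric(g_y)
  n <- length(x_bar)
  chi_bar <- as.matrix(chi_bar)
  V <- as.matrix(V)
  stopifnot(length(g_y) == n, all(dim(chi_bar) == n), all(dim(V) == n))
  if (!all(is.finite(x_bar)) || !all(is.finite(g_y))) {
    stop("non-finite entries in `x_bar` or `g_y`.", call. = FALSE)
  }
  S_chi <- chol_factor(chi_bar, "prior information (chi_bar)")
  S_V <- chol_factor(V, "observation-residue information (V)")
  structure(
    list(
      D = c(S_chi %*% x_bar, S_V %*% g_y),
      M = rbind(S_chi, S_V),
      S_chi = S_chi,
      S_V = S_V,
      n = n
    ),
    class = "augmented_system"
  )
}

#' Correntropy cost of a candidate state
#'
#' The objective maximised by the fixed-point iteration:
#' \deqn{J(x) = \frac{1}{2n} \sum_{i=1}^{2n} G_\sigma(d_i - m_i x),}
#' the mean Gaussian-kernel similarity over the \eqn{2n} whitened rows of the
#' augmented system. Bounded in `(0, 1]`, with 1 attained only when every
#' residual is exactly zero.
#'
#' @param x candidate state (length-n numeric).
#' @param sys an [build_augmented_system()] result.
#' @param sigma kernel bandwidth.
#' @return scalar cost in `(0, 1]`.
#' @export
correntropy_cost <- function(x, sys, sigma) {
  stopifnot(inherits(sys, "augmented_system"), length(x) == sys$n)
  mean(gaussian_kernel(sys$D - as.numeric(sys$M %*% x), sigma))
}

#' Fixed-point solver settings
#'
#' @param omega relative-change stopping tolerance for the iterates
#'   (`||x_t - x_{t-1}|| / (||x_{t-1}|| + 1e-12) <= omega`).
#' @param max_iter iteration cap.
#' @param min_sigma_guard bandwidths below this trigger a divergence warning
#'   before solving (small bandwidths can make the fixed-point map expansive).
#' @return list of class `fixed_point_settings`.
#' @export
fixed_point_settings <- function(omega = 1e-6, max_iter = 50L,
                                 min_sigma_guard = 0.05) {
  stopifnot(is.numeric(omega), omega > 0, max_iter >= 1)
  structure(list(omega = omega, max_iter = as.integer(max_iter),
                 min_sigma_guard = min_sigma_guard),
            class = "fixed_point_settings")
}

#' Maximum-correntropy state update by fixed-point (IRLS) iteration
#'
#' Solves the correntropy maximisation for one filter step. Each iteration
#' evaluates kernel weights at the previous iterate,
#' \eqn{C^{(t-1)} = \mathrm{diag}\, G_\sigma(D - M \hat x^{(t-1)})}, and
#' solves the weighted normal equations
#' \eqn{\hat x^{(t)} = (M^\top C^{(t-1)} M)^{-1} M^\top C^{(t-1)} D}
#' (equivalently the gain form, see [gain_form_update()]). The initial
#' iterate is the prior mean \eqn{\bar x_k}, so a zero-innovation step
#' terminates immediately.
#'
#' Convergence is declared when the relative iterate change drops below
#' `omega`, or when the kernel weights are stationary to within `1e-10`
#' (the iteration map depends on the state only through the weights, so
#' stationary weights imply the next iterate would be identical). With
#' `sigma = Inf` all weights are 1 and the solver returns the
#' information-filter posterior in a single iteration.
#'
#' @inheritParams build_augmented_system
#' @param sigma kernel bandwidth (`Inf` = least-squares limit).
#' @param settings a [fixed_point_settings()] object.
#' @return list of class `fixed_point_result`: `x_hat`, `iterations`,
#'   `converged`, `weights_chi`, `weights_V` (diagonals of
#'   \eqn{C_\chi, C_V} at the returned iterate's weights), and `sys`.
#' @export
fixed_point_solve <- function(x_bar, chi_bar, g_y, V, sigma,
                              settings = fixed_point_settings()) {
  check_bandwidth(sigma)
  stopifnot(inherits(settings, "fixed_point_settings"))
  sys <- build_augmented_system(x_bar, chi_bar, g_y, V)
  n <- sys$n
  if (sigma < settings$min_sigma_guard) {
    warning("kernel bandwidth ", sigma, " is below the divergence guard (",
            settings$min_sigma_guard, "); the fixed-point iteration may ",
            "diverge. Consider a larger bandwidth.", call. = FALSE)
  }
  scale_guard <- 1e6 * max(l2(sys$D), 1)

  x_old <- as.numeric(x_bar)
  w_old <- gaussian_kernel(sys$D - as.numeric(sys$M %*% x_old), sigma)
  iterations <- settings$max_iter
  converged <- FALSE
  x_new <- x_old
  w_new <- w_old

  for (t in seq_len(settings$max_iter)) {
    A <- crossprod(sys$M, w_old * sys$M)
    rhs <- crossprod(sys$M, w_old * sys$D)
    x_new <- tryCatch(
      as.numeric(solve(A, rhs)),
      error = function(e) {
        stop("weighted normal equations are numerically singular (all kernel ",
             "weights underflowed); increase the kernel bandwidth `sigma`.",
             call. = FALSE)
      }
    )
    if (!all(is.finite(x_new)) || l2(x_new) > scale_guard) {
      stop("fixed-point iteration diverged (iterate norm exceeded 1e6 times ",
           "the observation scale); increase the kernel bandwidth `sigma`.",
           call. = FALSE)
    }
    w_new <- gaussian_kernel(sys$D - as.numeric(sys$M %*% x_new), sigma)
    rel <- l2(x_new - x_old) / (l2(x_old) + 1e-12)
    if (rel <= settings$omega || max(abs(w_new - w_old)) <= 1e-10) {
      iterations <- t
      converged <- TRUE
      break
    }
    x_old <- x_new
    w_old <- w_new
  }

  structure(
    list(x_hat = x_new, iterations = iterations, converged = converged,
         weights_chi = w_new[seq_len(n)], weights_V = w_new[n + seq_len(n)],
         sys = sys),
    class = "fixed_point_result"
  )
}

#' Gain-form correntropy update
#'
#' The algebraically equivalent "Kalman gain" form of one IRLS iteration:
#' \deqn{\hat x = \bar x + (\tilde\chi + \tilde V)^{-1} \tilde V (g(y) - \bar x),}
#' where \eqn{\tilde\chi = S_\chi^\top C_\chi S_\chi} and
#' \eqn{\tilde V = S_V^\top C_V S_V} are the weight-revised prior and
#' observation information matrices. Equals the weighted-normal-equation
#' form on the same weights.
#'
#' @param x_bar prior mean.
#' @param chi_tilde revised prior information matrix (n x n, PSD).
#' @param V_tilde revised observation information matrix (n x n, PSD).
#' @param g_y pseudo-observation.
#' @return posterior mean (length-n numeric).
#' @export
gain_form_update <- function(x_bar, chi_tilde, V_tilde, g_y) {
  x_bar <- as.numeric(x_bar)
  g_y <- as.numeric(g_y)
  A <- symmetrize(as.matrix(chi_tilde) + as.matrix(V_tilde))
  gain <- tryCatch(
    solve(A, as.matrix(V_tilde)),
    error = function(e) stop("chi_tilde + V_tilde is singular.", call. = FALSE)
  )
  x_bar + as.numeric(gain %*% (g_y - x_bar))
}
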