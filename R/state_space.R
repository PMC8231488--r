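#' Fit the linear state-transition model from training trajectories
#'
#' Fits \eqn{x_k = F x_{k-1} + q_{k-1}} by ordinary least squares on
#' consecutive state pairs, and estimates the process-noise statistics from
#' the transition residues: \eqn{Q = \mathrm{cov}(x_k - F x_{k-1})} and the
#' process-noise information matrix \eqn{W = Q^{-1}} (jitter-regularised when
#' near-singular).
#'
#' @param states a data frame with state columns `x1..xn` (a `t` column and
#'   annotation columns are ignored), or a T x n numeric matrix of behavioural
#'   states ordered in time.
#' @param assume_zero_mean if `TRUE` (default) the process noise is assumed
#'   zero-mean and no intercept is fitted; if `FALSE` an intercept is fitted
#'   and folded into `q_mean`.
#' @return an object of class `state_space_model`: list with `n`, `F`,
#'   `q_mean`, `Q`, `W`.
#' @examples
#' set.seed(1)
#' X <- matrix(0, 500, 2)
#' for (k in 2:500) X[k, ] <- 0.9 * X[k - 1, ] + rnorm(2, sd = 0.1)
#' fit_transition(X)$F
#' @export
fit_transition <- function(states, assume_zero_mean = TRUE) {
  X <- as_state_matrix(states)
  storage.mode(X) <- "double"
  T_ <- nrow(X)
  n <- ncol(X)
  if (!all(is.finite(X))) stop("`states` contains non-finite values.", call. = FALSE)
  if (T_ < n + 1) stop("need at least n + 1 = ", n + 1, " time bins.", call. = FALSE)

  X_prev <- X[-T_, , drop = FALSE]
  X_next <- X[-1, , drop = FALSE]
  Z <- if (assume_zero_mean) X_prev else cbind(X_prev, 1)

  G <- crossprod(Z)
  qrG <- qr(G)
  if (qrG$rank < ncol(Z)) {
    deficient <- setdiff(seq_len(ncol(Z)), qrG$pivot[seq_len(qrG$rank)])
    stop("singular regressor Gram matrix: state dimension(s) ",
         paste(deficient[deficient <= n], collapse = ", "),
         " carry no independent variation; the transition fit is not ",
         "identified.", call. = FALSE)
  }
  B <- solve(G, crossprod(Z, X_next))        # (n[+1]) x n coefficients
  F_ <- t(B[seq_len(n), , drop = FALSE])
  q_mean <- if (assume_zero_mean) rep(0, n) else as.numeric(B[n + 1, ])

  resid <- X_next - Z %*% B
  Q <- symmetrize(stats::cov(resid))
  W <- inv_psd(Q, "process-noise covariance Q")

  structure(list(n = n, F = F_, q_mean = q_mean, Q = Q, W = W),
            class = "state_space_model")
}

#' Fit the linear tuning (observation) model for the Kalman-filter baseline
#'
#' Regresses each neural channel independently on the behavioural state:
#' \eqn{y_k = H x_k + \zeta_k}, each row of `H` describing how that channel's
#' activity tunes to the movement state. The intercepts are folded into the
#' residual mean `r_obs_mean`, and `R_obs` is the residual covariance
#' (diagonal by default, matching the channel-independence assumption of the
#' baseline).
#'
#' @param states data frame or T x n matrix of states.
#' @param firing data frame with channel columns `ch1..chm` or T x m matrix of
#'   binned counts/rates on the same time axis.
#' @param diagonal_R if `TRUE` (default) keep only the per-channel residual
#'   variances.
#' @param var_floor minimum residual variance per channel; channels with
#'   (near) zero residual variance are floored here with a warning.
#' @return an object of class `linear_tuning_model`: list with `H` (m x n),
#'   `r_obs_mean`, `R_obs`.
#' @export
fit_linear_tuning <- function(states, firing, diagonal_R = TRUE,
                              var_floor = 1e-8) {
  X <- as_state_matrix(states)
  Y <- as_state_matrix(firing, prefix = "ch")
  T_ <- nrow(X)
  n <- ncol(X)
  if (nrow(Y) != T_) stop("`states` and `firing` must share the time axis.", call. = FALSE)
  if (T_ < n + 1) stop("need at least n + 1 time bins.", call. = FALSE)

  Z <- cbind(X, 1)
  G <- crossprod(Z)
  if (qr(G)$rank < ncol(Z)) {
    stop("singular regressor Gram matrix: states do not span the state ",
         "space; the tuning fit is not identified.", call. = FALSE)
  }
  B <- solve(G, crossprod(Z, Y))             # (n+1) x m
  H <- t(B[seq_len(n), , drop = FALSE])      # m x n
  r_obs_mean <- as.numeric(B[n + 1, ])

  resid <- Y - Z %*% B
  v <- apply(resid, 2, stats::var)
  if (any(v < var_floor)) {
    warning(sum(v < var_floor), " channel(s) had residual variance below ",
            var_floor, "; floored.", call. = FALSE)
    v <- pmax(v, var_floor)
  }
  R_obs <- if (diagonal_R) diag(v, length(v)) else {
    R <- symmetrize(stats::cov(resid)); diag(R) <- pmax(diag(R), var_floor); R
  }

  structure(list(H = H, r_obs_mean = r_obs_mean, R_obs = R_obs),
            class = "linear_tuning_model")
}

#' Estimate residue mean, covariance and information matrix
#'
#' Summarises pseudo-observation (or process) residues by their sample mean
#' and covariance and returns the information matrix \eqn{V = R^{-1}} with
#' symmetric jitter regularisation. The filters assume zero-mean residues; a
#' flag is raised when the fitted mean is large relative to the state scale.
#'
#' @param residues T x n matrix or data frame of residues.
#' @param state_scale typical state magnitude used for the zero-mean check.
#' @param mean_warn_fraction warn when `||r_mean|| > mean_warn_fraction * state_scale`.
#' @return list of class `residue_stats`: `r_mean`, `R`, `V`,
#'   `mean_flagged` (logical).
#' @export
estimate_residue_information <- function(residues, state_scale = 1,
                                         mean_warn_fraction = 0.1) {
  E <- as_state_matrix(residues, prefix = "r")
  n <- ncol(E)
  if (nrow(E) < n + 1) stop("need at least n + 1 residue rows.", call. = FALSE)
  r_mean <- colMeans(E)
  R <- symmetrize(stats::cov(E))
  V <- inv_psd(R, "residue covariance R")
  flagged <- l2(r_mean) > mean_warn_fraction * state_scale
  if (flagged) {
    warning("residue mean (", signif(l2(r_mean), 3), ") exceeds ",
            mean_warn_fraction, " of the state scale; the zero-mean noise ",
            "assumption looks violated.", call. = FALSE)
  }
  structure(list(r_mean = r_mean, R = R, V = V, mean_flagged = flagged),
            class = "residue_stats")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat("<state_space_model> n =", x$n, "\nF:\n")
  print(round(x$F, 4))
  cat("tr(Q) =", signif(sum(diag(x$Q)), 4), "\n")
  invisible(x)
}
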