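#' One prediction step of the information filter
#'
#' Propagates the posterior through the linear dynamics:
#' \eqn{\bar x_k = F \hat x_{k-1} + \bar q} and
#' \deqn{\bar\chi_k = W - W F (\hat\chi_{k-1} + F^\top W F)^{-1} F^\top W,}
#' the information-form of \eqn{(F \hat P F^\top + Q)^{-1}}. Unlike the
#' covariance form it needs no inversion of \eqn{\hat\chi}, so a
#' near-total-uncertainty initialisation (\eqn{\hat\chi_0 = 10^{-6} I})
#' stays finite and positive semidefinite.
#'
#' @param x_hat posterior mean at k-1.
#' @param chi_hat posterior information matrix at k-1 (PSD).
#' @param model a [fit_transition()] `state_space_model`.
#' @return list with `x_bar`, `chi_bar`.
#' @export
ss_predict <- function(x_hat, chi_hat, model) {
  stopifnot(inherits(model, "state_space_model"))
  F_ <- model$F
  W <- model$W
  inner <- symmetrize(as.matrix(chi_hat) + t(F_) %*% W %*% F_)
  sol <- tryCatch(
    solve(inner, t(F_) %*% W),
    error = function(e) stop("prediction inner matrix (chi_hat + F'WF) is ",
                             "singular.", call. = FALSE)
  )
  list(
    x_bar = as.numeric(F_ %*% as.numeric(x_hat)) + model$q_mean,
    chi_bar = symmetrize(W - W %*% F_ %*% sol)
  )
}

#' Nonlinear information filter update
#'
#' The least-squares (sigma to infinity) special case of the correntropy
#' update: gain \eqn{K = (\bar\chi + V)^{-1} V}, posterior mean
#' \eqn{\hat x = \bar x + K (g(y) - \bar x)}, posterior information
#' \eqn{\hat\chi = \bar\chi + V}.
#'
#' @param x_bar,chi_bar prior mean and information matrix.
#' @param g_y pseudo-observation (length-n).
#' @param V observation-residue information matrix.
#' @return list with `x_hat`, `chi_hat`.
#' @export
nif_update <- function(x_bar, chi_bar, g_y, V) {
  x_bar <- as.numeric(x_bar)
  chi_hat <- symmetrize(as.matrix(chi_bar) + as.matrix(V))
  K <- tryCatch(
    solve(chi_hat, as.matrix(V)),
    error = function(e) stop("chi_bar + V is singular.", call. = FALSE)
  )
  list(x_hat = x_bar + as.numeric(K %*% (as.numeric(g_y) - x_bar)),
       chi_hat = chi_hat)
}

#' Maximum-correntropy information filter update
#'
#' Runs the whitened augmented regression and the fixed-point (IRLS) solver
#' for the posterior mean, then updates the posterior information matrix by
#' one of two variants:
#' \describe{
#'   \item{`"irls_B"` (default)}{\eqn{\hat\chi = M^\top C M =
#'     S_\chi^\top C_\chi S_\chi + S_V^\top C_V S_V} at the final weights —
#'     each whitened row contributes in proportion to its kernel weight, so
#'     an outlying row is discounted in the uncertainty too.}
#'   \item{`"asymptotic_A"`}{\eqn{\hat\chi = c(\sigma,\theta)\, M^\top M}
#'     with the asymptotic constant of [mcc_info_constant()]; valid in an
#'     asymptotic sense and mainly of interest for high-dimensional states.}
#' }
#' The published recursion also admits the opposite sandwich order
#' \eqn{S C S^\top}; it coincides with the default only for symmetric
#' factors and is exposed via `info_order = "scst"` for comparison.
#'
#' @inheritParams nif_update
#' @param sigma kernel bandwidth.
#' @param settings a [fixed_point_settings()].
#' @param variant `"irls_B"` or `"asymptotic_A"`.
#' @param theta reference residual standard deviation (required by variant A).
#' @param info_order `"mtcm"` (default, \eqn{M^\top C M}) or `"scst"`.
#' @return list with `x_hat`, `chi_hat`, `iterations`, `converged`,
#'   `weights_chi`, `weights_V`.
#' @export
nmcif_update <- function(x_bar, chi_bar, g_y, V, sigma,
                         settings = fixed_point_settings(),
                         variant = c("irls_B", "asymptotic_A"),
                         theta = NULL, info_order = c("mtcm", "scst")) {
  variant <- match.arg(variant)
  info_order <- match.arg(info_order)
  fp <- fixed_point_solve(x_bar, chi_bar, g_y, V, sigma, settings)
  sys <- fp$sys

  if (variant == "asymptotic_A") {
    if (is.null(theta)) {
      stop("variant \"asymptotic_A\" requires `theta`, the reference ",
           "residual standard deviation.", call. = FALSE)
    }
    chi_hat <- mcc_info_constant(sigma, theta) * crossprod(sys$M)
  } else if (info_order == "mtcm") {
    chi_hat <- crossprod(sys$S_chi, fp$weights_chi * sys$S_chi) +
      crossprod(sys$S_V, fp$weights_V * sys$S_V)
  } else {
    chi_hat <- sys$S_chi %*% (fp$weights_chi * t(sys$S_chi)) +
      sys$S_V %*% (fp$weights_V * t(sys$S_V))
  }

  list(x_hat = fp$x_hat, chi_hat = symmetrize(chi_hat),
       iterations = fp$iterations, converged = fp$converged,
       weights_chi = fp$weights_chi, weights_V = fp$weights_V)
}

#' One step of the covariance-form Kalman filter baseline
#'
#' Standard linear KF on the raw m-channel measurement with fitted tuning
#' model `y = H x + r_obs_mean + noise`.
#'
#' @param x,P previous posterior mean and covariance.
#' @param y raw m-vector measurement.
#' @param model `state_space_model`.
#' @param tuning `linear_tuning_model`.
#' @return list with `x`, `P`.
#' @export
kf_step <- function(x, P, y, model, tuning) {
  stopifnot(inherits(model, "state_space_model"),
            inherits(tuning, "linear_tuning_model"))
  F_ <- model$F
  H <- tuning$H
  x_bar <- as.numeric(F_ %*% as.numeric(x)) + model$q_mean
  P_bar <- symmetrize(F_ %*% as.matrix(P) %*% t(F_) + model$Q)
  innov <- as.numeric(y) - as.numeric(H %*% x_bar) - tuning$r_obs_mean
  S <- symmetrize(H %*% P_bar %*% t(H) + tuning$R_obs)
  K <- tryCatch(
    t(solve(S, H %*% P_bar)),
    error = function(e) stop("innovation covariance is singular.", call. = FALSE)
  )
  list(x = x_bar + as.numeric(K %*% innov),
       P = symmetrize((diag(nrow(P_bar)) - K %*% H) %*% P_bar))
}

new_decoding_result <- function(tbl, method, sigma = NA_real_,
                                settings = NULL, truncated_at = NA_integer_) {
  structure(tbl, class = c("decoding_result", class(tbl)),
            method = method, sigma = sigma, settings = settings,
            truncated_at = truncated_at)
}

#' Decode a trajectory with an information-type filter (or the raw observer)
#'
#' Runs a full per-step recursion over a pseudo-observation stream:
#' predict with the fitted linear dynamics, update with the chosen decoder.
#' Decoders: `"nmcif_b"` / `"nmcif_a"` (maximum-correntropy update with the
#' IRLS or asymptotic information matrix), `"nif"` (least-squares limit) and
#' `"nn"` (the pseudo-observations passed through untouched, i.e. the
#' observer used as a stand-alone decoder).
#'
#' If an update diverges, the result is truncated at that step (marked via
#' the `truncated_at` attribute and the `converged` column) rather than
#' returning silent NaNs.
#'
#' @param pseudo_obs data frame with columns `g1..gn` (e.g. from
#'   [predict.trained_observer()] or [simulate_pseudo_obs()]), or a T x n
#'   matrix.
#' @param model a `state_space_model`.
#' @param V observation-residue information matrix (n x n).
#' @param method decoder tag.
#' @param sigma kernel bandwidth for the correntropy decoders.
#' @param init_mean initial state estimate; defaults to the first row of
#'   `truth` when supplied, else zeros.
#' @param init_information initial information matrix (scalar or n x n);
#'   default `1e-6` encodes near-total initial uncertainty.
#' @param settings [fixed_point_settings()].
#' @param theta variant-A reference residual sd; defaults to 1 (whitened scale).
#' @param info_order see [nmcif_update()].
#' @param truth optional T x n matrix / data frame of ground-truth states to
#'   carry into the result.
#' @return a `decoding_result` tibble with columns `t`, `xhat1..n`,
#'   `truth1..n` (if given), `iterations`, `converged`.
#' @export
filter_trajectory <- function(pseudo_obs, model, V,
                              method = c("nmcif_b", "nmcif_a", "nif", "nn"),
                              sigma = 2,
                              init_mean = NULL, init_information = 1e-6,
                              settings = fixed_point_settings(),
                              theta = 1, info_order = "mtcm",
                              truth = NULL) {
  method <- match.arg(method)
  G <- as_state_matrix(pseudo_obs, prefix = "g")
  n <- model$n
  T_ <- nrow(G)
  Xt <- if (!is.null(truth)) as_state_matrix(truth) else NULL

  if (T_ == 0) {
    return(new_decoding_result(empty_result(n, !is.null(Xt)), method, sigma, settings))
  }
  stopifnot(ncol(G) == n)
  if (is.null(init_mean)) {
    init_mean <- if (!is.null(Xt)) Xt[1, ] else rep(0, n)
  }
  chi <- if (length(init_information) == 1) {
    diag(init_information, n)
  } else as.matrix(init_information)

  V <- as.matrix(V)
  x <- as.numeric(init_mean)
  est <- matrix(NA_real_, T_, n)
  iters <- rep(NA_integer_, T_)
  conv <- rep(NA, T_)
  truncated_at <- NA_integer_
  variant <- if (method == "nmcif_a") "asymptotic_A" else "irls_B"

  for (k in seq_len(T_)) {
    step <- tryCatch({
      if (method == "nn") {
        list(x_hat = G[k, ], chi_hat = chi, iterations = NA_integer_,
             converged = TRUE)
      } else {
        pr <- ss_predict(x, chi, model)
        if (method == "nif") {
          up <- nif_update(pr$x_bar, pr$chi_bar, G[k, ], V)
          list(x_hat = up$x_hat, chi_hat = up$chi_hat,
               iterations = 1L, converged = TRUE)
        } else {
          nmcif_update(pr$x_bar, pr$chi_bar, G[k, ], V, sigma, settings,
                       variant = variant, theta = theta,
                       info_order = info_order)
        }
      }
    }, error = function(e) e)
    if (inherits(step, "error")) {
      truncated_at <- k
      warning("decoder diverged at step ", k, ": ", conditionMessage(step),
              " Result truncated.", call. = FALSE)
      break
    }
    x <- step$x_hat
    chi <- step$chi_hat
    est[k, ] <- x
    iters[k] <- step$iterations
    conv[k] <- isTRUE(step$converged)
  }

  tbl <- tibble::tibble(t = seq_len(T_))
  for (j in seq_len(n)) tbl[[paste0("xhat", j)]] <- est[, j]
  if (!is.null(Xt)) for (j in seq_len(n)) tbl[[paste0("truth", j)]] <- Xt[, j]
  tbl$iterations <- iters
  tbl$converged <- conv
  if (!is.na(truncated_at)) tbl <- tbl[seq_len(truncated_at - 1), ]
  new_decoding_result(tbl, method, sigma, settings, truncated_at)
}

#' Decode a trajectory with the covariance-form Kalman filter baseline
#'
#' @param firing T x m matrix or data frame of raw measurements (`ch*` cols).
#' @param model a `state_space_model`.
#' @param tuning a `linear_tuning_model`.
#' @param init_mean initial mean (defaults to first truth row or zeros).
#' @param init_cov initial covariance (scalar or matrix; default 1).
#' @param truth optional ground truth.
#' @return a `decoding_result` tibble (same shape as [filter_trajectory()],
#'   `iterations` all `NA`).
#' @export
kf_trajectory <- function(firing, model, tuning, init_mean = NULL,
                          init_cov = 1, truth = NULL) {
  Y <- as_state_matrix(firing, prefix = "ch")
  n <- model$n
  T_ <- nrow(Y)
  Xt <- if (!is.null(truth)) as_state_matrix(truth) else NULL
  if (T_ == 0) {
    return(new_decoding_result(empty_result(n, !is.null(Xt)), "kf"))
  }
  if (is.null(init_mean)) init_mean <- if (!is.null(Xt)) Xt[1, ] else rep(0, n)
  P <- if (length(init_cov) == 1) diag(init_cov, n) else as.matrix(init_cov)

  x <- as.numeric(init_mean)
  est <- matrix(NA_real_, T_, n)
  truncated_at <- NA_integer_
  for (k in seq_len(T_)) {
    step <- tryCatch(kf_step(x, P, Y[k, ], model, tuning),
                     error = function(e) e)
    if (inherits(step, "error")) {
      truncated_at <- k
      warning("KF diverged at step ", k, "; result truncated.", call. = FALSE)
      break
    }
    x <- step$x
    P <- step$P
    est[k, ] <- x
  }
  tbl <- tibble::tibble(t = seq_len(T_))
  for (j in seq_len(n)) tbl[[paste0("xhat", j)]] <- est[, j]
  if (!is.null(Xt)) for (j in seq_len(n)) tbl[[paste0("truth", j)]] <- Xt[, j]
  tbl$iterations <- NA_integer_
  tbl$converged <- !is.na(est[, 1])
  if (!is.na(truncated_at)) tbl <- tbl[seq_len(truncated_at - 1), ]
  new_decoding_result(tbl, "kf", truncated_at = truncated_at)
}

empty_result <- function(n, with_truth) {
  tbl <- tibble::tibble(t = integer())
  for (j in seq_len(n)) tbl[[paste0("xhat", j)]] <- numeric()
  if (with_truth) for (j in seq_len(n)) tbl[[paste0("truth", j)]] <- numeric()
  tbl$iterations <- integer()
  tbl$converged <- logical()
  tbl
}
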