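#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted state-transition model
#'
#' One row per transition-matrix entry plus the process-noise covariance
#' entries, in long format.
#'
#' @param x a `state_space_model`.
#' @param ... unused.
#' @return tibble with columns `matrix`, `row`, `col`, `value`.
#' @export
tidy.state_space_model <- function(x, ...) {
  long <- function(M, name) tibble::tibble(
    matrix = name,
    row = rep(seq_len(nrow(M)), ncol(M)),
    col = rep(seq_len(ncol(M)), each = nrow(M)),
    value = as.numeric(M))
  dplyr::bind_rows(long(x$F, "F"), long(x$Q, "Q"))
}

#' @rdname tidy.state_space_model
#' @export
glance.state_space_model <- function(x, ...) {
  tibble::tibble(n = x$n,
                 spectral_radius = max(Mod(eigen(x$F, only.values = TRUE)$values)),
                 tr_Q = sum(diag(x$Q)))
}

#' Tidy a linear tuning model
#'
#' @param x a `linear_tuning_model`.
#' @param ... unused.
#' @return tibble with one row per channel/state-dimension weight.
#' @export
tidy.linear_tuning_model <- function(x, ...) {
  m <- nrow(x$H); n <- ncol(x$H)
  tibble::tibble(channel = rep(seq_len(m), n),
                 state_dim = rep(seq_len(n), each = m),
                 weight = as.numeric(x$H))
}

#' @rdname tidy.linear_tuning_model
#' @export
glance.linear_tuning_model <- function(x, ...) {
  tibble::tibble(m = nrow(x$H), n = ncol(x$H),
                 mean_residual_var = mean(diag(x$R_obs)))
}

#' Glance at a decoding result
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return one-row tibble: decoder tag, bandwidth, step count, 2D-MSE (when
#'   truth is available), mean/median fixed-point iterations, and whether the
#'   run was truncated by a divergence.
#' @export
glance.decoding_result <- function(x, ...) {
  has_truth <- any(grepl("^truth[0-9]+$", names(x)))
  tibble::tibble(
    method = attr(x, "method"),
    sigma = attr(x, "sigma"),
    n_steps = nrow(x),
    mse_2d = if (has_truth && nrow(x) > 0) as.numeric(mse_2d(x)) else NA_real_,
    mean_iterations = mean(x$iterations, na.rm = TRUE),
    median_iterations = stats::median(x$iterations, na.rm = TRUE),
    truncated = !is.na(attr(x, "truncated_at")))
}

#' @rdname glance.decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  n <- sum(grepl("^xhat[0-9]+$", names(x)))
  has_truth <- any(grepl("^truth[0-9]+$", names(x)))
  est <- tidyr::pivot_longer(
    tibble::as_tibble(x)[c("t", paste0("xhat", seq_len(n)))],
    -"t", names_to = "dim", names_prefix = "xhat", values_to = "estimate")
  if (has_truth) {
    tr <- tidyr::pivot_longer(
      tibble::as_tibble(x)[c("t", paste0("truth", seq_len(n)))],
      -"t", names_to = "dim", names_prefix = "truth", values_to = "truth")
    est <- dplyr::left_join(est, tr, by = c("t", "dim"))
  }
  dplyr::mutate(est, dim = as.integer(.data$dim))
}
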