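#' Read a trajectory from delimited-text files
#'
#' Reads the states file (columns `t, x1, x2, ...`) and optionally the firing
#' file (columns `t, ch1..chm`), both with a header row, and joins them on
#' the time column.
#'
#' @param states_path path to the states file.
#' @param firing_path optional path to the firing file.
#' @param bin_ms declared bin width (stored as an attribute; default 100 ms).
#' @return tibble with the state (and firing) columns; attribute `bin_ms`.
#' @export
read_trajectory <- function(states_path, firing_path = NULL, bin_ms = 100) {
  states <- readr::read_csv(states_path, show_col_types = FALSE)
  if (!"t" %in% names(states)) stop("states file must have a `t` column.", call. = FALSE)
  out <- states
  if (!is.null(firing_path)) {
    firing <- readr::read_csv(firing_path, show_col_types = FALSE)
    if (any(as.matrix(firing[grep("^ch", names(firing))]) < 0)) {
      stop("firing entries must be nonnegative.", call. = FALSE)
    }
    out <- dplyr::inner_join(states, firing, by = "t")
  }
  attr(out, "bin_ms") <- bin_ms
  out
}

#' Write trajectory tables to delimited text
#'
#' @param traj tibble with `t` plus state/firing columns.
#' @param states_path output path for the `t, x*` columns.
#' @param firing_path optional output path for the `t, ch*` columns.
#' @return invisibly, the input.
#' @export
write_trajectory <- function(traj, states_path, firing_path = NULL) {
  xcols <- grep("^(t|x[0-9]+)$", names(traj), value = TRUE)
  readr::write_csv(traj[xcols], states_path)
  if (!is.null(firing_path)) {
    ccols <- grep("^(t|ch[0-9]+)$", names(traj), value = TRUE)
    readr::write_csv(traj[ccols], firing_path)
  }
  invisible(traj)
}

as_plain <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = as.numeric(t(x)))  # row-major
  else x
}

from_plain <- function(x) {
  if (is.list(x) && !is.null(x$dim)) {
    matrix(unlist(x$data), nrow = unlist(x$dim)[1], byrow = TRUE)
  } else if (is.list(x)) {
    lapply(x, from_plain)
  } else x
}

#' Serialise fitted models to structured text (JSON)
#'
#' Writes a `state_space_model`, `linear_tuning_model`, `residue_stats` or
#' `trained_observer` to a JSON file with matrices stored as row-major lists.
#'
#' @param object the fitted model.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model_json <- function(object, path) {
  cls <- class(object)[1]
  payload <- switch(
    cls,
    state_space_model = list(n = object$n, F = as_plain(object$F),
                             q_mean = object$q_mean, Q = as_plain(object$Q),
                             W = as_plain(object$W)),
    linear_tuning_model = list(H = as_plain(object$H),
                               r_obs_mean = object$r_obs_mean,
                               R_obs = as_plain(object$R_obs)),
    residue_stats = list(r_mean = object$r_mean, R = as_plain(object$R),
                         V = as_plain(object$V)),
    trained_observer = list(
      n_hidden = object$config$n_hidden,
      history_bins = object$history_bins,
      wts = object$net$wts, n = object$net$n,
      center = object$center, scale = object$scale,
      residue = list(r_mean = object$residue$r_mean,
                     R = as_plain(object$residue$R),
                     V = as_plain(object$residue$V)),
      held_out_mse = object$held_out_mse),
    stop("unsupported object class: ", cls, call. = FALSE)
  )
  jsonlite::write_json(c(list(class = cls), payload), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialised by [write_model_json()]
#'
#' @param path path to the JSON file.
#' @return the reconstructed model object (for `trained_observer`, a list
#'   with the stored weights and constants; the forward pass is available
#'   via the stored `nnet` structure only after retraining, so the residue
#'   statistics and architecture are what round-trips).
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- raw$class
  raw$class <- NULL
  obj <- lapply(raw, from_plain)
  structure(obj, class = cls)
}

#' Write a decoding result and its summary
#'
#' Per-step estimates as delimited text plus a JSON summary (2D-MSE, mean
#' iterations, decoder settings echo).
#'
#' @param result a `decoding_result`.
#' @param csv_path output path for the per-step table.
#' @param summary_path optional output path for the JSON summary.
#' @return invisibly, `result`.
#' @export
write_decoding_result <- function(result, csv_path, summary_path = NULL) {
  readr::write_csv(tibble::as_tibble(result), csv_path)
  if (!is.null(summary_path)) {
    g <- glance(result)
    g$mse_convention <- "sum_over_dims"
    jsonlite::write_json(as.list(g), summary_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(result)
}
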