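#' 2-D mean squared decoding error
#'
#' \eqn{\mathrm{MSE} = \frac{1}{T}\sum_k \|\hat x_k - x_k\|^2}: squared
#' Euclidean error summed over the state dimensions, averaged over time.
#' This is the summation convention under which the published decoding
#' errors for states in `[-1, 1]` (around 0.25-0.58) are on the expected
#' scale; the alternative mean-over-dimensions convention is available via
#' `average_dims = TRUE` and is recorded in the attribute `convention`.
#'
#' @param estimates a `decoding_result` (its `xhat*`/`truth*` columns are
#'   used), or a T x n matrix / data frame of estimates.
#' @param truth T x n matrix / data frame of true states (ignored when
#'   `estimates` carries its own `truth*` columns).
#' @param average_dims divide by the state dimension as well (default FALSE).
#' @return scalar MSE with attribute `convention`.
#' @export
mse_2d <- function(estimates, truth = NULL, average_dims = FALSE) {
  if (is.data.frame(estimates) && any(grepl("^truth[0-9]+$", names(estimates)))) {
    E <- as_state_matrix(as.data.frame(estimates), prefix = "xhat")
    Tr <- as_state_matrix(as.data.frame(estimates), prefix = "truth")
  } else {
    if (is.null(truth)) stop("`truth` is required.", call. = FALSE)
    E <- as_state_matrix(estimates, prefix = "xhat")
    Tr <- as_state_matrix(truth)
  }
  if (nrow(E) == 0) stop("empty estimates.", call. = FALSE)
  stopifnot(all(dim(E) == dim(Tr)))
  out <- mean(rowSums((E - Tr)^2))
  if (average_dims) out <- out / ncol(E)
  attr(out, "convention") <- if (average_dims) "mean_over_dims" else "sum_over_dims"
  out
}

#' Percentage decrease between two error levels
#'
#' `100 * (a - b) / a`: by how many percent `b` undercuts the reference `a`.
#' The convention used when comparing decoders' mean errors.
#'
#' @param a reference (e.g. baseline decoder mean error).
#' @param b comparison value.
#' @return percentage (vectorised).
#' @export
pct_decrease <- function(a, b) 100 * (a - b) / a

#' Summarise per-segment decoding errors
#'
#' @param mse numeric vector of per-segment 2D-MSEs, or a list of
#'   `decoding_result` objects (each scored with [mse_2d()]).
#' @param decoder decoder tag carried into the summary.
#' @param condition condition tag.
#' @return a one-row tibble of class `segment_summary` with `decoder`,
#'   `condition`, `n_segments`, `mean`, `sd` (sample sd; 0 with a warning for
#'   a single segment) and the per-segment values as a list column `mse`.
#' @export
summarize_segments <- function(mse, decoder = NA_character_,
                               condition = NA_character_) {
  if (is.list(mse) && !is.numeric(mse)) {
    mse <- vapply(mse, function(r) as.numeric(mse_2d(r)), 0)
  }
  if (length(mse) < 1) stop("need at least one segment.", call. = FALSE)
  s <- if (length(mse) == 1) {
    warning("single segment; sd reported as 0.", call. = FALSE)
    0
  } else stats::sd(mse)
  out <- tibble::tibble(decoder = decoder, condition = condition,
                        n_segments = length(mse),
                        mean = mean(mse), sd = s, mse = list(as.numeric(mse)))
  class(out) <- c("segment_summary", class(out))
  out
}

#' Published reference decoding errors for the two-lever task
#'
#' Returns the published 2D-MSE benchmark table (mean +/- sd over 10 test
#' segments, two subjects) for the decoders compared by this package, as
#' shipped in `inst/extdata/benchmark_2dmse.csv`. Used as the input to the
#' percentage-decrease arithmetic.
#'
#' @return tibble with columns `condition`, `method`, `subject`, `mean`, `sd`.
#' @export
reference_benchmarks <- function() {
  path <- system.file("extdata", "benchmark_2dmse.csv", package = "mcdecode")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Run one of the benchmark experiments end to end
#'
#' Orchestrates the simulated analogue of the published comparisons on a
#' [make_benchmark_suite()] bundle: fits the state-transition and tuning
#' models on the training block, decodes every test segment with the
#' requested decoders, and returns per-segment and summary tables.
#'
#' Conditions:
#' \describe{
#'   \item{`clean`}{all decoders, defaults to well-informed initialisation;}
#'   \item{`bad_init`}{decoders initialised at truth + `init_offset`
#'     (information filters with information `1e-6 I`, KF with covariance
#'     `I`);}
#'   \item{`contaminated`}{shot-noise pseudo-observations;}
#'   \item{`bandwidth_sweep`}{NMCIF-B across `sigma_grid` on the
#'     contaminated segments, reporting error and fixed-point iteration
#'     statistics per bandwidth.}
#' }
#'
#' @param condition experiment name.
#' @param suite a [make_benchmark_suite()] bundle.
#' @param decoders decoder tags among `"kf"`, `"nn"`, `"nif"`, `"nmcif_a"`,
#'   `"nmcif_b"`.
#' @param sigma kernel bandwidth for the correntropy decoders (default 2).
#' @param sigma_grid bandwidth grid for `bandwidth_sweep`.
#' @param observer `"oracle"` uses the bundle's synthetic pseudo-observations
#'   (residue information known exactly); `"mlp"` trains a
#'   [train_observer()] on the training block and decodes its predictions.
#' @param observer_cfg [observer_config()] for `observer = "mlp"`.
#' @param settings [fixed_point_settings()].
#' @return list of class `experiment_report`: `summary` (tibble of
#'   per-decoder mean +/- sd), `per_segment` (long tibble), `trajectories`
#'   (list of `decoding_result`s of the first segment, for plotting), and
#'   for the sweep a `sweep` tibble (per-sigma error and iteration stats).
#' @export
run_experiment <- function(condition = c("clean", "bad_init", "contaminated",
                                         "bandwidth_sweep"),
                           suite = make_benchmark_suite(),
                           decoders = c("kf", "nn", "nif", "nmcif_b"),
                           sigma = 2,
                           sigma_grid = c(0.5, 1, 2, 5, 10, 100),
                           observer = c("oracle", "mlp"),
                           observer_cfg = observer_config(n_restarts = 5L),
                           settings = fixed_point_settings()) {
  condition <- match.arg(condition)
  observer <- match.arg(observer)
  stopifnot(inherits(suite, "benchmark_suite"))
  bad <- setdiff(decoders, c("kf", "nn", "nif", "nmcif_a", "nmcif_b"))
  if (length(bad)) stop("unknown decoder(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)

  model <- fit_transition(suite$train$states)
  tuning <- fit_linear_tuning(suite$train$states, suite$train$firing)

  if (observer == "mlp") {
    obs_fit <- train_observer(suite$train$firing, suite$train$states,
                              observer_cfg)
    V <- obs_fit$residue$V
    get_pseudo <- function(seg) stats::predict(obs_fit, seg$firing)
  } else {
    obs_fit <- NULL
    V <- solve(suite$pseudo_R)
    get_pseudo <- function(seg) seg$pseudo_obs
  }

  obs_key <- if (condition == "contaminated" || condition == "bandwidth_sweep") {
    function(seg) if (observer == "oracle") seg$pseudo_obs_contaminated else {
      # contaminate the observer outputs with the bundle's shot spec
      contaminate_observations(get_pseudo(seg), suite$contamination_fraction,
                               suite$contamination_magnitude,
                               baseline_var = diag(solve(V)),
                               seed = suite$seed + 7L)
    }
  } else get_pseudo

  offset <- if (condition == "bad_init") suite$init_offset else NULL

  decode_segment <- function(seg, decoder, sig) {
    truth <- seg$states
    init_mean <- if (is.null(offset)) NULL else
      as_state_matrix(truth)[1, ] + offset
    if (decoder == "kf") {
      kf_trajectory(seg$firing, model, tuning, init_mean = init_mean,
                    init_cov = 1, truth = truth)
    } else {
      filter_trajectory(obs_key(seg), model, V, method = decoder,
                        sigma = sig, init_mean = init_mean,
                        init_information = 1e-6, settings = settings,
                        truth = truth)
    }
  }

  if (condition == "bandwidth_sweep") {
    rows <- list()
    trajectories <- list()
    for (sig in sigma_grid) {
      res <- lapply(suite$segments, decode_segment, decoder = "nmcif_b",
                    sig = sig)
      trajectories[[as.character(sig)]] <- res[[1]]
      iters <- unlist(lapply(res, function(r) r$iterations))
      rows[[as.character(sig)]] <- tibble::tibble(
        sigma = sig,
        mean_mse = mean(vapply(res, function(r) as.numeric(mse_2d(r)), 0)),
        median_iterations = stats::median(iters, na.rm = TRUE),
        mean_iterations = mean(iters, na.rm = TRUE))
    }
    sweep_tbl <- dplyr::bind_rows(rows)
    out <- list(condition = condition, sweep = sweep_tbl,
                trajectories = trajectories, seed = suite$seed)
    class(out) <- "experiment_report"
    return(out)
  }

  per_segment <- list()
  summaries <- list()
  trajectories <- list()
  for (decoder in decoders) {
    res <- lapply(suite$segments, decode_segment, decoder = decoder,
                  sig = sigma)
    trajectories[[decoder]] <- res[[1]]
    m <- vapply(res, function(r) as.numeric(mse_2d(r)), 0)
    per_segment[[decoder]] <- tibble::tibble(
      decoder = decoder, segment = seq_along(m), mse = m)
    summaries[[decoder]] <- summarize_segments(m, decoder, condition)
  }
  out <- list(condition = condition,
              summary = dplyr::bind_rows(summaries),
              per_segment = dplyr::bind_rows(per_segment),
              trajectories = trajectories,
              observer = obs_fit, seed = suite$seed)
  class(out) <- "experiment_report"
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", x$condition, "\n")
  if (!is.null(x$summary)) print(as.data.frame(x$summary[c(
    "decoder", "condition", "n_segments", "mean", "sd")]))
  if (!is.null(x$sweep)) print(as.data.frame(x$sweep))
  invisible(x)
}
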