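#' Build lagged firing-rate features
#'
#' Concatenates the current bin with `history_bins` past bins per channel, so
#' row `k` is `[y_k, y_{k-1}, ..., y_{k-history_bins}]`. At the default 100 ms
#' binning, `history_bins = 4` gives the current bin plus 400 ms of history.
#' Leading rows are padded by repeating the first bin, keeping the output
#' aligned to the state at bin `k` without discarding trial starts.
#'
#' @param firing T x m matrix or data frame with channel columns `ch1..chm`.
#' @param history_bins number of past bins to append (default 4).
#' @return T x (m * (history_bins + 1)) numeric matrix.
#' @export
make_lagged_features <- function(firing, history_bins = 4L) {
  Y <- as_state_matrix(firing, prefix = "ch")
  stopifnot(history_bins >= 0)
  T_ <- nrow(Y)
  if (T_ <= history_bins) {
    stop("need more than `history_bins` = ", history_bins, " time bins.",
         call. = FALSE)
  }
  blocks <- lapply(0:history_bins, function(l) {
    idx <- pmax(seq_len(T_) - l, 1L)   # repeat-first-bin padding
    Y[idx, , drop = FALSE]
  })
  do.call(cbind, blocks)
}

#' Observer training configuration
#'
#' @param n_hidden hidden units of the single-hidden-layer network (default 10).
#' @param history_bins past bins appended to the current bin (default 4,
#'   i.e. 400 ms of history at 100 ms bins).
#' @param n_restarts random weight initialisations; the restart with the
#'   lowest held-out MSE is kept (default 20).
#' @param train_fraction fraction of rows used for weight fitting; the rest
#'   is the held-out split (default 0.6).
#' @param max_iter optimiser iteration cap per restart.
#' @param decay weight decay.
#' @param random_split if `FALSE` (default) the split is contiguous in time
#'   (first `train_fraction` of rows) to avoid temporal leakage; `TRUE`
#'   samples rows at random.
#' @param seed base RNG seed; restart `r` uses `seed + r`.
#' @return list of class `observer_config`.
#' @export
observer_config <- function(n_hidden = 10L, history_bins = 4L,
                            n_restarts = 20L, train_fraction = 0.6,
                            max_iter = 300L, decay = 1e-4,
                            random_split = FALSE, seed = 1L) {
  stopifnot(n_hidden >= 1, history_bins >= 0,
            train_fraction > 0, train_fraction < 1, n_restarts >= 1)
  structure(list(n_hidden = as.integer(n_hidden),
                 history_bins = as.integer(history_bins),
                 n_restarts = as.integer(n_restarts),
                 train_fraction = train_fraction,
                 max_iter = as.integer(max_iter), decay = decay,
                 random_split = random_split, seed = as.integer(seed)),
            class = "observer_config")
}

#' Train the nonlinear observer g(.)
#'
#' Fits a single-hidden-layer feed-forward network mapping lagged
#' high-dimensional firing rates to the low-dimensional behavioural state,
#' giving the pseudo-observation model \eqn{g(y_k) = x_k + r_k} with an
#' identity observation matrix. Inputs are standardised; training minimises
#' mean squared error (via [nnet::nnet()] with linear outputs) from
#' `n_restarts` seeded initialisations, and the restart with the lowest
#' held-out MSE is kept (ties broken by the lowest restart index). The
#' residue statistics `(r_mean, R, V)` consumed by the filters are estimated
#' on the training-split residuals.
#'
#' @param firing T x m firing matrix or data frame (`ch*` columns).
#' @param states T x n state matrix or data frame (`x*` columns).
#' @param config an [observer_config()].
#' @return object of class `trained_observer`: the selected network, input
#'   standardisation constants, per-restart held-out MSEs, selected restart,
#'   and `residue` ([estimate_residue_information()] output).
#' @export
train_observer <- function(firing, states, config = observer_config()) {
  stopifnot(inherits(config, "observer_config"))
  X <- as_state_matrix(states)
  Phi <- make_lagged_features(firing, config$history_bins)
  T_ <- nrow(Phi)
  stopifnot(nrow(X) == T_)

  n_train <- floor(config$train_fraction * T_)
  if (n_train < 2 || n_train >= T_) stop("degenerate train/held-out split.", call. = FALSE)
  if (config$random_split) {
    set.seed(config$seed)
    idx_train <- sort(sample.int(T_, n_train))
  } else {
    idx_train <- seq_len(n_train)
  }
  idx_val <- setdiff(seq_len(T_), idx_train)

  center <- colMeans(Phi[idx_train, , drop = FALSE])
  scale_ <- apply(Phi[idx_train, , drop = FALSE], 2, stats::sd)
  scale_[scale_ < 1e-8] <- 1
  Z <- sweep(sweep(Phi, 2, center), 2, scale_, "/")

  val_mse <- rep(NA_real_, config$n_restarts)
  nets <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    set.seed(config$seed + r)
    net <- tryCatch(
      nnet::nnet(x = Z[idx_train, , drop = FALSE],
                 y = X[idx_train, , drop = FALSE],
                 size = config$n_hidden, linout = TRUE, trace = FALSE,
                 maxit = config$max_iter, decay = config$decay,
                 MaxNWts = 1e5),
      error = function(e) NULL
    )
    if (is.null(net) || !all(is.finite(net$wts))) {
      warning("restart ", r, " diverged; skipped.", call. = FALSE)
      next
    }
    pred <- stats::predict(net, Z[idx_val, , drop = FALSE])
    val_mse[r] <- mean(rowSums((pred - X[idx_val, , drop = FALSE])^2))
    nets[[r]] <- net
  }
  if (all(is.na(val_mse))) stop("all observer restarts diverged.", call. = FALSE)
  best <- which.min(val_mse)   # ties: lowest restart index

  net <- nets[[best]]
  resid_train <- stats::predict(net, Z[idx_train, , drop = FALSE]) -
    X[idx_train, , drop = FALSE]
  residue <- suppressWarnings(
    estimate_residue_information(resid_train,
                                 state_scale = max(stats::sd(X), 1e-6))
  )

  structure(
    list(net = net, center = center, scale = scale_,
         history_bins = config$history_bins, config = config,
         val_mse = val_mse, best_restart = best,
         held_out_mse = val_mse[best], residue = residue),
    class = "trained_observer"
  )
}

#' Apply a trained observer to firing data
#'
#' Deterministic forward pass producing the pseudo-observation stream
#' \eqn{g(y_k)} for a whole trajectory (lagging and standardisation are
#' applied internally).
#'
#' @param object a [train_observer()] result.
#' @param firing T x m firing matrix or data frame with the same channel
#'   width used in training.
#' @param ... unused.
#' @return a tibble with columns `g1..gn`.
#' @export
predict.trained_observer <- function(object, firing, ...) {
  Phi <- make_lagged_features(firing, object$history_bins)
  if (ncol(Phi) != length(object$center)) {
    stop("feature width ", ncol(Phi), " does not match the trained width ",
         length(object$center), ".", call. = FALSE)
  }
  Z <- sweep(sweep(Phi, 2, object$center), 2, object$scale, "/")
  G <- stats::predict(object$net, Z)
  colnames(G) <- paste0("g", seq_len(ncol(G)))
  tibble::as_tibble(G)
}

#' @export
print.trained_observer <- function(x, ...) {
  cat("<trained_observer>", x$config$n_hidden, "hidden units,",
      length(x$center), "inputs; held-out MSE",
      signif(x$held_out_mse, 4), "(restart", paste0(x$best_restart, ")"), "\n")
  invisible(x)
}
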