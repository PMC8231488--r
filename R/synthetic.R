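#' Two-lever task scenario
#'
#' Describes the simulated rodent two-lever discrimination task used to
#' exercise the decoders: each trial rests at state `[0, 0]`, ramps along a
#' sigmoid to the drawn lever target — `[1, 1]` for the high lever, `[1, -1]`
#' for the low lever — holds it, then returns to rest along a sigmoid.
#'
#' @param n_trials number of trials.
#' @param p_high probability a trial is a high-lever trial (default 0.4,
#'   echoing the typical high/low imbalance in this task).
#' @param bin_ms bin width in milliseconds (default 100).
#' @param pre_cue_bins rest bins before the start cue (default 5 = 500 ms).
#' @param press_approach_bins ramp bins from rest to the lever (default 5).
#' @param hold_bins bins held at the lever target (default 5, i.e. the
#'   minimum 500 ms hold).
#' @param return_bins ramp bins back to rest after feedback (default 2 =
#'   200 ms).
#' @param sigmoid_steepness logistic steepness per bin for the ramps
#'   (default 1.5).
#' @param seed RNG seed for the lever draws.
#' @return list of class `task_scenario`.
#' @export
task_scenario <- function(n_trials = 20L, p_high = 0.4, bin_ms = 100,
                          pre_cue_bins = 5L, press_approach_bins = 5L,
                          hold_bins = 5L, return_bins = 2L,
                          sigmoid_steepness = 1.5, seed = 1L) {
  stopifnot(n_trials >= 1, p_high >= 0, p_high <= 1,
            pre_cue_bins >= 1, press_approach_bins >= 1,
            hold_bins >= 1, return_bins >= 1)
  structure(list(n_trials = as.integer(n_trials), p_high = p_high,
                 bin_ms = bin_ms, pre_cue_bins = as.integer(pre_cue_bins),
                 press_approach_bins = as.integer(press_approach_bins),
                 hold_bins = as.integer(hold_bins),
                 return_bins = as.integer(return_bins),
                 sigmoid_steepness = sigmoid_steepness,
                 targets = list(rest = c(0, 0), high = c(1, 1), low = c(1, -1)),
                 seed = as.integer(seed)),
            class = "task_scenario")
}

# Monotone logistic ramp of length L normalised to start exactly at 0 and
# end exactly at 1.
sigmoid_ramp <- function(L, steepness) {
  if (L == 1) return(1)
  v <- stats::plogis(steepness * (seq_len(L) - (L + 1) / 2))
  (v - v[1]) / (v[L] - v[1])
}

#' Simulate behavioural states for the two-lever task
#'
#' Generates the concatenated, sigmoid-smoothed 2-D state trajectory of a
#' [task_scenario()]: per trial, a rest plateau at `[0, 0]`, a monotone
#' sigmoid rise to the drawn lever target, a hold plateau exactly at the
#' target, and a sigmoid return to rest. Deterministic given the scenario
#' seed.
#'
#' @param scenario a [task_scenario()].
#' @return a tibble with columns `t` (bin index), `x1`, `x2`, `trial`,
#'   `lever` (`"high"`/`"low"`), `phase`
#'   (`"rest"`, `"approach"`, `"hold"`, `"return"`).
#' @export
simulate_states <- function(scenario = task_scenario()) {
  stopifnot(inherits(scenario, "task_scenario"))
  set.seed(scenario$seed)
  levers <- ifelse(stats::runif(scenario$n_trials) < scenario$p_high,
                   "high", "low")
  # a session always contains both trial types (as in the real task); without
  # this the second state dimension is perfectly collinear with the first and
  # model fitting is unidentified
  if (scenario$n_trials >= 2 && length(unique(levers)) == 1) {
    levers[scenario$n_trials] <- setdiff(c("high", "low"), levers[1])
  }
  up <- sigmoid_ramp(scenario$press_approach_bins, scenario$sigmoid_steepness)
  down <- 1 - sigmoid_ramp(scenario$return_bins, scenario$sigmoid_steepness)

  trials <- lapply(seq_len(scenario$n_trials), function(i) {
    target <- scenario$targets[[levers[i]]]
    ramp <- c(rep(0, scenario$pre_cue_bins), up,
              rep(1, scenario$hold_bins), down)
    phase <- c(rep("rest", scenario$pre_cue_bins),
               rep("approach", scenario$press_approach_bins),
               rep("hold", scenario$hold_bins),
               rep("return", scenario$return_bins))
    tibble::tibble(x1 = ramp * target[1], x2 = ramp * target[2],
                   trial = i, lever = levers[i], phase = phase)
  })
  out <- dplyr::bind_rows(trials)
  dplyr::mutate(out, t = dplyr::row_number(), .before = 1)
}

#' Neural tuning specification for the synthetic recording
#'
#' Describes how the simulated multi-channel activity tunes to the 2-D state.
#' Two generative modes: `"lnp_poisson"` (default) draws per-bin spike counts
#' from a linear-nonlinear-Poisson model,
#' \eqn{y_{k,c} \sim \mathrm{Pois}(\exp(a_c^\top x_k + b_c))}, with gains
#' scaled so counts are O(0-5) per 100 ms bin as in cortical recordings;
#' `"linear_gaussian"` gives \eqn{y_k = A x_k + b + \epsilon} and is used
#' where exactness matters.
#'
#' @param m channel count (default 32).
#' @param mode `"lnp_poisson"` or `"linear_gaussian"`.
#' @param A optional m x 2 tuning matrix (drawn from the spec's default
#'   ranges when `NULL`).
#' @param b optional m-vector of baselines.
#' @param noise_sd Gaussian noise sd (linear mode only).
#' @param seed seed for drawing `A`, `b`.
#' @return list of class `tuning_spec`.
#' @export
tuning_spec <- function(m = 32L, mode = c("lnp_poisson", "linear_gaussian"),
                        A = NULL, b = NULL, noise_sd = 1, seed = 1L) {
  mode <- match.arg(mode)
  m <- as.integer(m)
  set.seed(seed)
  if (is.null(A)) {
    A <- if (mode == "lnp_poisson") {
      matrix(stats::runif(m * 2, -0.25, 0.25), m, 2)
    } else {
      matrix(stats::runif(m * 2, -1, 1), m, 2)
    }
  }
  if (is.null(b)) {
    b <- if (mode == "lnp_poisson") rep(log(1.5), m) else stats::runif(m, 0, 1)
  }
  stopifnot(nrow(A) == m, length(b) == m)
  structure(list(m = m, mode = mode, A = A, b = b, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tuning_spec")
}

#' Simulate multi-channel firing from states
#'
#' @param states tibble/matrix of states (`x*` columns).
#' @param tuning a [tuning_spec()].
#' @param seed RNG seed for the noise/count draws.
#' @return tibble with columns `t`, `ch1..chm`.
#' @export
simulate_firing <- function(states, tuning = tuning_spec(), seed = 1L) {
  stopifnot(inherits(tuning, "tuning_spec"))
  X <- as_state_matrix(states)
  T_ <- nrow(X)
  eta <- X %*% t(tuning$A)
  eta <- sweep(eta, 2, tuning$b, "+")
  set.seed(seed)
  Y <- if (tuning$mode == "linear_gaussian") {
    eta + matrix(stats::rnorm(T_ * tuning$m, sd = tuning$noise_sd), T_, tuning$m)
  } else {
    if (any(eta > 30)) {
      stop("LNP rate exponent exceeds 30 (rate overflow); use smaller ",
           "tuning gains.", call. = FALSE)
    }
    matrix(stats::rpois(T_ * tuning$m, lambda = exp(eta)), T_, tuning$m)
  }
  colnames(Y) <- paste0("ch", seq_len(tuning$m))
  out <- tibble::as_tibble(Y)
  dplyr::mutate(out, t = seq_len(T_), .before = 1)
}

#' Simulate an oracle pseudo-observation stream
#'
#' Emulates the output of a converged nonlinear observer: the true state plus
#' zero-mean Gaussian residue with known covariance `R`,
#' \eqn{g(y_k) = x_k + r_k}. Useful for studying the filters in isolation
#' from observer-training noise (the residue information fed to the filters
#' is then exactly `solve(R)`).
#'
#' @param states tibble/matrix of true states.
#' @param R residue covariance (n x n matrix, or a scalar for `R = r I`).
#' @param seed RNG seed.
#' @return tibble with columns `t`, `g1..gn`.
#' @export
simulate_pseudo_obs <- function(states, R = 0.15, seed = 1L) {
  X <- as_state_matrix(states)
  n <- ncol(X)
  R <- if (length(R) == 1) diag(R, n) else as.matrix(R)
  set.seed(seed)
  Er <- matrix(stats::rnorm(nrow(X) * n), nrow(X), n) %*% chol(R)
  G <- X + Er
  colnames(G) <- paste0("g", seq_len(n))
  out <- tibble::as_tibble(G)
  dplyr::mutate(out, t = seq_len(nrow(X)), .before = 1)
}

#' Contaminate observations with heavy-tailed shot noise
#'
#' Adds zero-mean Gaussian shots with variance
#' `magnitude * baseline_var` to a seeded random subset of exactly
#' `floor(fraction * T)` time bins (all columns of a contaminated bin are
#' hit), emulating the occasional large recording artefacts seen in online
#' neural data. Clean bins are preserved bitwise.
#'
#' @param obs tibble with a `t` column plus value columns, or a matrix.
#' @param fraction fraction of bins to contaminate (default 0.033).
#' @param magnitude variance multiplier for the shots (default 100).
#' @param baseline_var baseline residual variance per value column (vector
#'   recycled as needed). This should be the clean residue variance, e.g.
#'   `diag(R)` of the pseudo-observation model.
#' @param seed RNG seed.
#' @return the input with contaminated values and a logical `outlier` column;
#'   the contaminated bin indices are also attached as attribute
#'   `outlier_idx`.
#' @export
contaminate_observations <- function(obs, fraction = 0.033, magnitude = 100,
                                     baseline_var, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1, magnitude > 0)
  is_df <- is.data.frame(obs)
  vals <- if (is_df) {
    cols <- setdiff(names(obs), c("t", "trial", "lever", "phase", "outlier"))
    as.matrix(obs[cols])
  } else as.matrix(obs)
  T_ <- nrow(vals)
  n_out <- floor(fraction * T_)
  set.seed(seed)
  idx <- if (n_out > 0) sort(sample.int(T_, n_out)) else integer()
  sds <- sqrt(magnitude * rep_len(baseline_var, ncol(vals)))
  if (n_out > 0) {
    shots <- matrix(stats::rnorm(n_out * ncol(vals)), n_out) %*% diag(sds, ncol(vals))
    vals[idx, ] <- vals[idx, , drop = FALSE] + shots
  }
  if (is_df) {
    out <- obs
    out[colnames(vals)] <- tibble::as_tibble(vals)
    out$outlier <- seq_len(T_) %in% idx
  } else {
    out <- vals
  }
  attr(out, "outlier_idx") <- idx
  out
}

#' Generate the three-condition benchmark bundle
#'
#' Builds a fully-labelled synthetic session mirroring the experimental
#' protocol used to compare the decoders: a training block for model fitting
#' and, per condition, `n_segments` held-out test segments over which
#' decoding error is summarised as mean +/- sd. The three conditions share
#' identical underlying states and clean measurements:
#' \describe{
#'   \item{clean}{states, firing and pseudo-observations as generated;}
#'   \item{bad_init}{same data, decoders to be initialised at truth plus
#'     `init_offset`;}
#'   \item{contaminated}{the clean pseudo-observations with shot noise on a
#'     `contamination_fraction` of bins (clean bins bitwise identical).}
#' }
#'
#' @param seed master seed; all internal draws derive from it.
#' @param n_train_trials trials in the training block (default 30).
#' @param n_segments test segments per condition (default 10).
#' @param trials_per_segment trials per test segment (default 4).
#' @param tuning a [tuning_spec()].
#' @param pseudo_R oracle pseudo-observation residue covariance
#'   (scalar or matrix; default `0.15`, i.e. sd ~0.39 per dimension against a
#'   state range of `[-1, 1]`).
#' @param contamination_fraction fraction of contaminated bins (default 0.033).
#' @param contamination_magnitude shot variance multiplier (default 100).
#' @param init_offset decoder initialisation offset for the bad_init
#'   condition (default `c(3, 3)`).
#' @param scenario_args extra arguments passed to [task_scenario()].
#' @return list of class `benchmark_suite` with elements `train` (list:
#'   `states`, `firing`, `pseudo_obs`), `segments` (list of `n_segments`
#'   lists with `states`, `firing`, `pseudo_obs`, `pseudo_obs_contaminated`),
#'   `pseudo_R`, `init_offset`, `seed`.
#' @export
make_benchmark_suite <- function(seed = 1L, n_train_trials = 30L,
                                 n_segments = 10L, trials_per_segment = 4L,
                                 tuning = tuning_spec(),
                                 pseudo_R = 0.15,
                                 contamination_fraction = 0.033,
                                 contamination_magnitude = 100,
                                 init_offset = c(3, 3),
                                 scenario_args = list()) {
  seed <- as.integer(seed)
  n <- 2L
  Rmat <- if (length(pseudo_R) == 1) diag(pseudo_R, n) else as.matrix(pseudo_R)

  make_block <- function(block_seed, n_trials) {
    scen <- do.call(task_scenario,
                    c(list(n_trials = n_trials, seed = block_seed),
                      scenario_args))
    states <- simulate_states(scen)
    list(states = states,
         firing = simulate_firing(states, tuning, seed = block_seed + 1L),
         pseudo_obs = simulate_pseudo_obs(states, Rmat, seed = block_seed + 2L))
  }

  train <- make_block(seed, n_train_trials)
  segments <- lapply(seq_len(n_segments), function(s) {
    blk <- make_block(seed + 100L * s, trials_per_segment)
    blk$pseudo_obs_contaminated <- contaminate_observations(
      blk$pseudo_obs, contamination_fraction, contamination_magnitude,
      baseline_var = diag(Rmat), seed = seed + 100L * s + 3L)
    blk
  })

  structure(list(train = train, segments = segments, pseudo_R = Rmat,
                 init_offset = init_offset, seed = seed,
                 contamination_fraction = contamination_fraction,
                 contamination_magnitude = contamination_magnitude),
            class = "benchmark_suite")
}
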