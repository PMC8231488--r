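# Shared fixture builders (all generated in code; nothing on disk).

# Random symmetric positive definite matrix.
rand_spd <- function(n, jitter = 0.1) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(jitter, n)
}

# A small decoding scenario: fitted dynamics from a training block plus one
# test segment of oracle pseudo-observations.
small_scenario <- function(seed = 1, n_train_trials = 8, n_test_trials = 3,
                           pseudo_R = 0.15) {
  suite <- make_benchmark_suite(seed = seed, n_train_trials = n_train_trials,
                                n_segments = 1,
                                trials_per_segment = n_test_trials,
                                pseudo_R = pseudo_R)
  list(model = fit_transition(suite$train$states),
       tuning = fit_linear_tuning(suite$train$states, suite$train$firing),
       V = solve(suite$pseudo_R),
       R = suite$pseudo_R,
       train = suite$train,
       seg = suite$segments[[1]],
       suite = suite)
}

# Simulate a linear-Gaussian AR(1) state sequence x_k = F x_{k-1} + N(0, Q).
simulate_ar1 <- function(F_, Q, T_, seed = 1) {
  set.seed(seed)
  n <- nrow(F_)
  S <- chol(Q)
  X <- matrix(0, T_, n)
  for (k in 2:T_) {
    X[k, ] <- as.numeric(F_ %*% X[k - 1, ]) + as.numeric(rnorm(n) %*% S)
  }
  X
}

# First step at which trajectory `a` is within `eps` of trajectory `b`
# (Euclidean distance on the estimates), Inf if never.
first_step_within <- function(a, b, eps = 0.2) {
  ca <- grep("^xhat[0-9]+$", names(a), value = TRUE)
  d <- sqrt(rowSums((as.matrix(a[ca]) - as.matrix(b[ca]))^2))
  w <- which(d <= eps)
  if (length(w)) w[1] else Inf
}
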