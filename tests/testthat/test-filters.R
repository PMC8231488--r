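test_that("prediction step matches the covariance-form propagation", {
  # scalar closed form: F = W = chi = 1 gives chi_bar = 0.5
  m1 <- structure(list(n = 1L, F = matrix(1), q_mean = 0, Q = matrix(1),
                       W = matrix(1)), class = "state_space_model")
  pr <- ss_predict(0, matrix(1), m1)
  expect_equal(as.numeric(pr$chi_bar), 0.5)

  # total initial uncertainty stays finite and PSD without inverting chi_hat
  pr0 <- ss_predict(c(1, 1), matrix(0, 2, 2),
                    structure(list(n = 2L, F = diag(0.9, 2), q_mean = c(0, 0),
                                   Q = diag(0.5, 2), W = diag(2, 2)),
                              class = "state_space_model"))
  expect_true(all(is.finite(pr0$chi_bar)))
  expect_true(all(eigen(pr0$chi_bar, symmetric = TRUE)$values > -1e-12))

  # matrix-inversion-lemma oracle on a random 3-D instance
  set.seed(6)
  F_ <- matrix(rnorm(9, sd = 0.4), 3)
  Q <- rand_spd(3)
  chi_hat <- rand_spd(3)
  m3 <- structure(list(n = 3L, F = F_, q_mean = rep(0, 3), Q = Q,
                       W = solve(Q)), class = "state_space_model")
  pr3 <- ss_predict(rnorm(3), chi_hat, m3)
  direct <- solve(F_ %*% solve(chi_hat) %*% t(F_) + Q)
  expect_equal(pr3$chi_bar, direct, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("information-filter update respects the trust limits", {
  chi <- rand_spd(2)
  x_bar <- c(1, -1)
  g <- c(3, 2)
  up0 <- nif_update(x_bar, chi, g, matrix(0, 2, 2))
  expect_equal(up0$x_hat, x_bar)
  expect_equal(up0$chi_hat, chi, ignore_attr = TRUE)
  upg <- nif_update(x_bar, diag(1e-12, 2), g, diag(10, 2))
  expect_equal(upg$x_hat, g, tolerance = 1e-10)
})

test_that("information and covariance forms decode identically (duality oracle)", {
  sc <- small_scenario(seed = 4, n_train_trials = 10, n_test_trials = 30)
  G <- sc$seg$pseudo_obs
  truth <- sc$seg$states
  expect_gte(nrow(G), 500)
  G <- G[1:500, ]
  truth <- truth[1:500, ]
  x0 <- as_matrix0 <- c(0, 0)
  nif <- filter_trajectory(G, sc$model, sc$V, method = "nif",
                           init_mean = x0, init_information = diag(2),
                           truth = truth)
  # covariance-form KF on the identity pseudo-observation model
  tun <- structure(list(H = diag(2), r_obs_mean = c(0, 0), R_obs = sc$R),
                   class = "linear_tuning_model")
  kf <- kf_trajectory(G[, c("g1", "g2")] |> setNames(c("ch1", "ch2")),
                      sc$model, tun, init_mean = x0, init_cov = diag(2),
                      truth = truth)
  expect_lt(max(abs(as.matrix(nif[, c("xhat1", "xhat2")]) -
                    as.matrix(kf[, c("xhat1", "xhat2")]))), 1e-8)
})

test_that("correntropy update with infinite bandwidth is exactly the information filter", {
  set.seed(10)
  chi <- rand_spd(2)
  V <- rand_spd(2)
  x_bar <- rnorm(2)
  g <- rnorm(2)
  nif <- nif_update(x_bar, chi, g, V)
  mc <- nmcif_update(x_bar, chi, g, V, sigma = Inf)
  expect_equal(mc$x_hat, nif$x_hat, tolerance = 1e-12)
  expect_equal(mc$chi_hat, nif$chi_hat, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(mc$iterations, 1L)
})

test_that("asymptotic information variant scales M'M and needs theta", {
  set.seed(13)
  chi <- rand_spd(2)
  V <- rand_spd(2)
  x_bar <- rnorm(2)
  g <- rnorm(2)
  expect_error(nmcif_update(x_bar, chi, g, V, sigma = 2,
                            variant = "asymptotic_A", theta = NULL), "theta")
  # sigma -> infinity limit: chi_hat -> M'M / theta^2 = (chi + V) / theta^2
  mcA <- nmcif_update(x_bar, chi, g, V, sigma = 1e8,
                      variant = "asymptotic_A", theta = 1)
  expect_equal(mcA$chi_hat, chi + V, tolerance = 1e-6, ignore_attr = TRUE)
  mcA2 <- nmcif_update(x_bar, chi, g, V, sigma = 2,
                       variant = "asymptotic_A", theta = 1)
  expect_equal(mcA2$chi_hat, mcc_info_constant(2, 1) * (chi + V),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Kalman baseline ignores uninformative measurements and locks onto exact ones", {
  model <- structure(list(n = 2L, F = diag(2), q_mean = c(0, 0),
                          Q = diag(0.01, 2), W = diag(100, 2)),
                     class = "state_space_model")
  H <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
  # huge measurement noise: posterior ~ prior
  tun_bad <- structure(list(H = H, r_obs_mean = rep(0, 3),
                            R_obs = diag(1e12, 3)),
                       class = "linear_tuning_model")
  st <- kf_step(c(1, -1), diag(2), c(0, 0, 0), model, tun_bad)
  expect_equal(st$x, c(1, -1), tolerance = 1e-6)

  # zero process noise + exact observations of a fixed state: mean converges
  model0 <- structure(list(n = 2L, F = diag(2), q_mean = c(0, 0),
                           Q = diag(1e-12, 2), W = diag(1e12, 2)),
                      class = "state_space_model")
  tun <- structure(list(H = H, r_obs_mean = rep(0, 3), R_obs = diag(0.01, 3)),
                   class = "linear_tuning_model")
  x_true <- c(0.5, -0.2)
  x <- c(5, 5); P <- diag(2)
  for (k in 1:200) {
    st <- kf_step(x, P, as.numeric(H %*% x_true), model0, tun)
    x <- st$x; P <- st$P
  }
  expect_equal(x, x_true, tolerance = 1e-3)
})

test_that("posterior information stays PSD along whole decoded trajectories", {
  sc <- small_scenario(seed = 17, n_train_trials = 8, n_test_trials = 2)
  for (method in c("nif", "nmcif_b", "nmcif_a")) {
    x <- c(0, 0); chi <- diag(1e-6, 2)
    for (k in seq_len(nrow(sc$seg$pseudo_obs))) {
      pr <- ss_predict(x, chi, sc$model)
      up <- if (method == "nif") {
        c(nif_update(pr$x_bar, pr$chi_bar, as.numeric(sc$seg$pseudo_obs[k, c("g1", "g2")]), sc$V),
          list(iterations = 1L))
      } else {
        nmcif_update(pr$x_bar, pr$chi_bar,
                     as.numeric(sc$seg$pseudo_obs[k, c("g1", "g2")]), sc$V,
                     sigma = 2, variant = if (method == "nmcif_a") "asymptotic_A" else "irls_B",
                     theta = 1)
      }
      x <- up$x_hat; chi <- up$chi_hat
      expect_true(all(eigen(chi, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
    }
  }
})

test_that("a gross outlier barely moves the correntropy filter but drags the information filter", {
  sc <- small_scenario(seed = 23)
  x_bar <- c(0.5, 0.5)
  chi <- diag(5, 2)
  g_clean <- c(0.6, 0.4)
  g_out <- g_clean + c(1e6, 0)
  nif_shift <- sqrt(sum((nif_update(x_bar, chi, g_out, sc$V)$x_hat -
                         nif_update(x_bar, chi, g_clean, sc$V)$x_hat)^2))
  mc_shift <- sqrt(sum((nmcif_update(x_bar, chi, g_out, sc$V, sigma = 2)$x_hat -
                        nmcif_update(x_bar, chi, g_clean, sc$V, sigma = 2)$x_hat)^2))
  expect_lt(mc_shift, 0.2)          # bounded influence
  expect_gt(nif_shift, 1e4)         # linear influence
  expect_lt(mc_shift, nif_shift)
  # beyond e = sigma the pull of a growing outlier decreases
  shift_at <- function(mag) {
    sqrt(sum((nmcif_update(x_bar, chi, g_clean + c(mag, 0), sc$V, sigma = 2)$x_hat -
              nmcif_update(x_bar, chi, g_clean, sc$V, sigma = 2)$x_hat)^2))
  }
  expect_gt(shift_at(1), shift_at(100))
  expect_gte(shift_at(100), shift_at(1e6))  # weights underflow to equality
})

test_that("trajectory decoding handles empty input and forgets the prior", {
  sc <- small_scenario(seed = 31, n_test_trials = 3)
  empty <- filter_trajectory(sc$seg$pseudo_obs[0, ], sc$model, sc$V, "nif")
  expect_identical(nrow(empty), 0L)

  # NIF trajectories from different vague initial information coincide
  r1 <- filter_trajectory(sc$seg$pseudo_obs, sc$model, sc$V, "nif",
                          init_mean = c(0, 0), init_information = 1e-6,
                          truth = sc$seg$states)
  r2 <- filter_trajectory(sc$seg$pseudo_obs, sc$model, sc$V, "nif",
                          init_mean = c(0, 0), init_information = 1e-8,
                          truth = sc$seg$states)
  after20 <- function(r) as.matrix(r[-(1:20), c("xhat1", "xhat2")])
  expect_lt(max(abs(after20(r1) - after20(r2))), 1e-4)
})

test_that("decoding results carry tidy/glance/plot interfaces", {
  sc <- small_scenario(seed = 37, n_test_trials = 2)
  r <- filter_trajectory(sc$seg$pseudo_obs, sc$model, sc$V, "nmcif_b",
                         sigma = 2, truth = sc$seg$states)
  g <- glance(r)
  expect_identical(g$method, "nmcif_b")
  expect_true(is.finite(g$mse_2d))
  td <- tidy(r)
  expect_setequal(names(td), c("t", "dim", "estimate", "truth"))
  expect_s3_class(autoplot(r), "ggplot")
})
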