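test_that("augmented system reproduces the scalar and identity-whitening cases", {
  # scalar: chi = 4, V = 9 -> S_chi = 2, S_V = 3, D = [2, 6], M = [2, 3]'
  sys <- build_augmented_system(1, matrix(4), 2, matrix(9))
  expect_equal(as.numeric(sys$S_chi), 2)
  expect_equal(as.numeric(sys$S_V), 3)
  expect_equal(sys$D, c(2, 6))
  expect_equal(as.numeric(sys$M), c(2, 3))

  # identity information: M stacks two identities, D stacks the inputs
  sys2 <- build_augmented_system(c(1, -1), diag(2), c(0.5, 2), diag(2))
  expect_equal(sys2$M, rbind(diag(2), diag(2)))
  expect_equal(sys2$D, c(1, -1, 0.5, 2))
})

test_that("Cholesky factors reconstruct the information blocks and whiten the noise", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 3
    chi <- rand_spd(n)
    V <- rand_spd(n)
    sys <- build_augmented_system(rnorm(n), chi, rnorm(n), V)
    # factor-multiply-back oracle
    expect_equal(crossprod(sys$S_chi), chi, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(crossprod(sys$S_V), V, tolerance = 1e-10, ignore_attr = TRUE)
    # whitening: cov(S delta) = S cov(delta) S' = I for cov = info^-1
    expect_equal(sys$S_chi %*% solve(chi) %*% t(sys$S_chi), diag(n),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # unweighted normal equations recover the information-filter sum
    expect_equal(crossprod(sys$M), chi + V, tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(build_augmented_system(0, matrix(-1), 0, matrix(1)), "prior")
  expect_error(build_augmented_system(0, matrix(1), 0, matrix(-1)), "residue")
})

test_that("correntropy cost is 1 at a perfect fit and bounded above by 1", {
  set.seed(7)
  chi <- rand_spd(2)
  V <- rand_spd(2)
  x <- rnorm(2)
  sys <- build_augmented_system(x, chi, x, V)  # D = M x exactly
  expect_equal(correntropy_cost(x, sys, 1.3), 1)
  for (cand in replicate(20, rnorm(2), simplify = FALSE)) {
    val <- correntropy_cost(cand, sys, 1.3)
    expect_true(val > 0 && val <= 1)
  }
})

test_that("fixed point returns the prior immediately on zero innovation", {
  chi <- rand_spd(2)
  V <- rand_spd(2)
  x_bar <- c(0.3, -1)
  for (sigma in c(0.5, 2, 100, Inf)) {
    r <- fixed_point_solve(x_bar, chi, x_bar, V, sigma)
    expect_equal(r$x_hat, x_bar)
    expect_identical(r$iterations, 1L)
    expect_true(r$converged)
  }
})

test_that("infinite bandwidth solves in one iteration and equals the information-filter posterior", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(1:4, 1)
    chi <- rand_spd(n)
    V <- rand_spd(n)
    x_bar <- rnorm(n)
    g <- rnorm(n)
    nif <- as.numeric(x_bar + solve(chi + V) %*% V %*% (g - x_bar))
    r <- fixed_point_solve(x_bar, chi, g, V, Inf)
    expect_identical(r$iterations, 1L)
    expect_equal(r$x_hat, nif, tolerance = 1e-10)
    expect_equal(c(r$weights_chi, r$weights_V), rep(1, 2 * n))
  }
})

test_that("scalar fixed-point solution matches the grid-search argmax of the cost", {
  # reference instance chi = V = 1, x_bar = 0, g = 5, sigma = 2: the cost is
  # symmetric with two equal global maxima; the solution must sit on one of
  # them (ties on the grid are resolved to within its resolution)
  sys0 <- build_augmented_system(0, matrix(1), 5, matrix(1))
  r0 <- fixed_point_solve(0, matrix(1), 5, matrix(1), 2,
                          fixed_point_settings(omega = 1e-10, max_iter = 200))
  grid <- seq(-2, 7, by = 1e-4)
  costs <- vapply(grid, function(x) correntropy_cost(x, sys0, 2), 0)
  top <- grid[costs >= max(costs) - 1e-12]
  expect_lt(min(abs(r0$x_hat - top)), 1e-4)

  set.seed(101)
  for (rep in 1:30) {
    chi <- matrix(runif(1, 0.5, 2))
    V <- matrix(runif(1, 0.5, 2))
    x_bar <- rnorm(1)
    sigma <- runif(1, 1, 3)
    # innovations inside the kernel's unimodal regime: beyond it the cost is
    # multimodal and the fixed point tracks the mode nearest the prior
    g <- x_bar + runif(1, -1, 1) * sigma / sqrt(max(chi, V))
    r <- fixed_point_solve(x_bar, chi, g, V, sigma,
                           fixed_point_settings(omega = 1e-10, max_iter = 200))
    sys <- build_augmented_system(x_bar, chi, g, V)
    grid <- seq(min(x_bar, g) - 1, max(x_bar, g) + 1, by = 1e-4)
    costs <- vapply(grid, function(x) correntropy_cost(x, sys, sigma), 0)
    expect_lt(abs(r$x_hat - grid[which.max(costs)]), 1e-4)
  }
})

test_that("IRLS normal equations and the gain form agree per iteration", {
  set.seed(5)
  for (rep in 1:100) {
    n <- sample(1:5, 1)
    chi <- rand_spd(n)
    V <- rand_spd(n)
    x_bar <- rnorm(n)
    g <- rnorm(n)
    sigma <- runif(1, 0.8, 4)
    sys <- build_augmented_system(x_bar, chi, g, V)
    # one IRLS iteration from a random iterate, both routes
    x_it <- rnorm(n)
    w <- gaussian_kernel(sys$D - as.numeric(sys$M %*% x_it), sigma)
    irls <- as.numeric(solve(crossprod(sys$M, w * sys$M),
                             crossprod(sys$M, w * sys$D)))
    chi_t <- crossprod(sys$S_chi, w[1:n] * sys$S_chi)
    V_t <- crossprod(sys$S_V, w[n + 1:n] * sys$S_V)
    expect_equal(gain_form_update(x_bar, chi_t, V_t, g), irls,
                 tolerance = 1e-10)
  }
})

test_that("gain form handles the degenerate trust limits", {
  chi <- rand_spd(2)
  V <- rand_spd(2)
  x_bar <- c(1, 2)
  g <- c(-3, 0.5)
  expect_equal(gain_form_update(x_bar, chi, matrix(0, 2, 2), g), x_bar)
  expect_equal(gain_form_update(x_bar, matrix(0, 2, 2), V, g), g)
  expect_error(gain_form_update(x_bar, matrix(0, 2, 2), matrix(0, 2, 2), g),
               "singular")
})

test_that("weights stay in (0,1] and the solution does not lower the cost below the prior's", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(1:3, 1)
    chi <- rand_spd(n)
    V <- rand_spd(n)
    x_bar <- rnorm(n)
    g <- rnorm(n, sd = 2)
    sigma <- runif(1, 1, 5)
    r <- fixed_point_solve(x_bar, chi, g, V, sigma)
    w <- c(r$weights_chi, r$weights_V)
    expect_true(all(w > 0 & w <= 1))
    sys <- build_augmented_system(x_bar, chi, g, V)
    expect_gte(correntropy_cost(r$x_hat, sys, sigma),
               correntropy_cost(x_bar, sys, sigma) - 1e-12)
  }
})

test_that("iteration count decreases with the kernel bandwidth on a fixed scenario", {
  set.seed(2024)
  instances <- replicate(40, {
    n <- 2
    list(chi = rand_spd(n), V = rand_spd(n), x_bar = rnorm(n), g = rnorm(n, sd = 2))
  }, simplify = FALSE)
  med_iters <- vapply(c(1, 2, 5, 10, 100), function(sigma) {
    stats::median(vapply(instances, function(ins) {
      fixed_point_solve(ins$x_bar, ins$chi, ins$g, ins$V, sigma)$iterations
    }, 0L))
  }, 0)
  expect_true(all(diff(med_iters) <= 0))
})

test_that("a tiny bandwidth triggers the divergence guard warning", {
  expect_warning(
    fixed_point_solve(0, matrix(1), 1, matrix(1), 0.01),
    "diverge"
  )
})
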