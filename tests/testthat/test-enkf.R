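test_that("parameter transforms round-trip and keep positivity", {
  lay <- state_layout(3, 0, c("mu", "lam"), log_params = TRUE)
  expect_equal(untransform_params(c(0, 0), lay), c(1, 1))
  expect_equal(transform_params(exp(c(-2.3, 0.5)), lay), c(-2.3, 0.5))
  v <- c(0.08, 0.2)
  expect_equal(untransform_params(transform_params(v, lay), lay), v)
  expect_error(transform_params(c(-1, 1), lay), "> 0")
  lay2 <- state_layout(3, 0, c("a", "b"), log_params = c(TRUE, FALSE))
  expect_equal(untransform_params(c(0, -5), lay2), c(1, -5))
})

test_that("initial ensembles are Gaussian, reproducible and validated", {
  lay <- state_layout(2, 0, "p")
  x0 <- c(1, 2, 0.5)
  # zero covariance: all members identical
  e0 <- init_ensemble(x0, rep(0, 3), 5, lay, seed = 1)
  expect_equal(e0$X, matrix(x0, 3, 5))
  # determinism under a fixed seed
  e1 <- init_ensemble(x0, c(1, 2, 0.1), 50, lay, seed = 42)
  e2 <- init_ensemble(x0, c(1, 2, 0.1), 50, lay, seed = 42)
  expect_identical(e1$X, e2$X)
  # law of large numbers at large M
  M <- 1e5
  P0 <- matrix(c(2, 0.5, 0, 0.5, 1, 0, 0, 0, 0.2), 3, 3)
  eb <- init_ensemble(x0, P0, M, lay, seed = 7)
  st <- ensemble_stats(eb)
  expect_equal(st$mean, x0, tolerance = 4 * sqrt(2 / M) / min(abs(x0)))
  expect_lt(max(abs(st$cov - P0)), 4 * max(diag(P0)) * sqrt(2 / M) * 3)
  # non-PSD covariance rejected with the offending eigenvalue
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(init_ensemble(c(0, 0), bad, 10, state_layout(2, 0, character(0))),
               "eigenvalue")
  expect_error(init_ensemble(x0, c(1, -0.1, 1), 10, lay), "variance")
})

test_that("ensemble statistics use the unbiased covariance", {
  lay <- state_layout(3, 0, character(0))
  x <- c(1, -2, 0.5)
  e <- structure(list(X = cbind(x, -x), layout = lay, M = 2L),
                 class = "ensemble")
  st <- ensemble_stats(e)
  expect_equal(st$mean, c(0, 0, 0))
  expect_equal(st$cov, 2 * tcrossprod(x)) # M - 1 = 1 denominator
  # brute force on a fixed 5-member ensemble
  set.seed(9)
  X <- matrix(rnorm(15), 3, 5)
  st2 <- ensemble_stats(X)
  mu <- rowMeans(X)
  brute <- matrix(0, 3, 3)
  for (i in 1:5) brute <- brute + tcrossprod(X[, i] - mu)
  expect_equal(st2$cov, brute / 4)
  expect_equal(ensemble_stats(X, full = FALSE)$var, diag(st2$cov))
  # identical members: zero covariance
  expect_equal(ensemble_stats(matrix(1, 3, 4))$cov, matrix(0, 3, 3))
})

test_that("predicted observation statistics include R exactly", {
  lay <- state_layout(3, 0, character(0))
  X <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  e <- structure(list(X = X, layout = lay, M = 4L), class = "ensemble")
  h <- function(X) X[1:2, , drop = FALSE]
  R <- c(0.5, 0.25)
  ps <- predict_observations(e, h, R)
  expect_equal(ps$P_zz, diag(R))          # identical members: only R remains
  expect_equal(ps$P_xz, matrix(0, 3, 2))
  # linear measurement: P_zz = H P H^T + R
  set.seed(21)
  X2 <- matrix(rnorm(3 * 200), 3, 200)
  e2 <- structure(list(X = X2, layout = lay, M = 200L), class = "ensemble")
  H <- matrix(c(1, 0, 2, 1, 0, -1), 2, 3)
  ps2 <- predict_observations(e2, function(X) H %*% X, R)
  P <- ensemble_stats(X2)$cov
  expect_equal(ps2$P_zz, H %*% P %*% t(H) + diag(R), tolerance = 1e-12)
  expect_equal(ps2$P_xz, P %*% t(H), tolerance = 1e-12)
  expect_error(predict_observations(e2, function(X) H %*% X, diag(3)),
               "2-dim")
})

test_that("Kalman gain solves the linear system to inverse accuracy", {
  expect_equal(kalman_gain(matrix(0, 3, 2), diag(2)), matrix(0, 3, 2))
  expect_equal(drop(kalman_gain(matrix(2), matrix(4))), 0.5)
  set.seed(13)
  A <- matrix(rnorm(16), 4, 4)
  P_zz <- crossprod(A) + diag(4)
  P_xz <- matrix(rnorm(24), 6, 4)
  expect_equal(kalman_gain(P_xz, P_zz), P_xz %*% solve(P_zz),
               tolerance = 1e-10)
  expect_error(kalman_gain(matrix(1, 2, 2), matrix(1, 2, 2)), "singular")
})

test_that("update is a no-op for zero cross-covariance or huge R", {
  lay <- state_layout(2, 0, character(0))
  X <- matrix(rep(c(1, 2), 5), 2, 5)   # identical members: P_xz = 0, K = 0
  e <- structure(list(X = X, layout = lay, M = 5L), class = "ensemble")
  up <- enkf_update(e, z = c(5, 5), h = function(X) X, R = c(1, 1))
  expect_equal(up$ensemble$X, X)
  expect_equal(up$gain_norm, 0)
  # huge R: gain vanishes, posterior ~ prior
  set.seed(2)
  X2 <- matrix(rnorm(2 * 50), 2, 50)
  e2 <- structure(list(X = X2, layout = lay, M = 50L), class = "ensemble")
  spread <- sqrt(max(ensemble_stats(X2, full = FALSE)$var))
  up2 <- enkf_update(e2, c(0, 0), function(X) X, R = c(1e12, 1e12))
  expect_lt(max(abs(up2$ensemble$X - X2)), 1e-3 * spread)
})

test_that("reported posterior covariance obeys the gain identity", {
  # post cov must equal prior cov - K P_zz K^T, element by element
  lay <- state_layout(3, 0, character(0))
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(3 * 40), 3, 40)
    e <- structure(list(X = X, layout = lay, M = 40L), class = "ensemble")
    H <- matrix(rnorm(6), 2, 3)
    R <- c(0.3, 0.7)
    ps <- predict_observations(e, function(X) H %*% X, R)
    K <- kalman_gain(ps$P_xz, ps$P_zz)
    up <- enkf_update(e, rnorm(2), function(X) H %*% X, R, obs = ps)
    explicit <- ensemble_stats(X, full = FALSE)$var - diag(K %*% ps$P_zz %*% t(K))
    expect_equal(up$post_var, explicit, tolerance = 1e-10)
  }
})

test_that("forecast performs Euler steps and leaves parameters drift-free", {
  g <- small_grid(n_age = 50)
  model <- toy_filter_model(g)
  p <- toy_ref()
  x0 <- c(toy_density(grid_ages(g), 2, p), log(p$mu), log(p$lam))
  e <- init_ensemble(x0, rep(0, 52), 3, model$layout, seed = 1)
  # zero rate, zero noise: unchanged
  e_still <- enkf_forecast(e, function(X, t) 0 * X, 2, 0.1)
  expect_equal(e_still$X, e$X)
  # closed-form one-step increment at the member's own parameters
  e_fwd <- enkf_forecast(e, model$rate_fn, 2, 0.1)
  expect_equal(e_fwd$X[1:50, 1],
               x0[1:50] + 0.1 * toy_rate_of_change(grid_ages(g), 2, p))
  expect_equal(e_fwd$X[51:52, ], e$X[51:52, ]) # parameters untouched
  # non-finite derivatives are reported with member and entry
  expect_error(enkf_forecast(e, function(X, t) X * NaN, 2, 0.1), "member")
})

test_that("ensemble filter tracks the exact scalar Kalman recursion", {
  a <- 0.95; q <- 0.02; r <- 0.1
  m0 <- 1; p0 <- 1
  n_steps <- 20
  set.seed(77)
  x_true <- numeric(n_steps); x <- 2
  for (k in 1:n_steps) {
    x <- a * x + rnorm(1, sd = sqrt(q)); x_true[k] <- x
  }
  z <- x_true + rnorm(n_steps, sd = sqrt(r))
  oracle <- scalar_kf(z, a, q, r, m0, p0)
  M <- 1e5
  lay <- state_layout(1, 0, character(0))
  ens <- init_ensemble(m0, p0, M, lay, seed = 78)
  rate <- function(X, t) (a - 1) / 0.1 * X # Euler with dt = 0.1 gives x -> a x
  for (k in 1:n_steps) {
    ens <- enkf_forecast(ens, rate, 0, 0.1, process_noise("diag", sqrt(q)))
    up <- enkf_update(ens, z[k], function(X) X, r)
    ens <- up$ensemble
    st <- ensemble_stats(ens, full = FALSE)
    se_mean <- sqrt(oracle$var[k] / M)
    se_var <- oracle$var[k] * sqrt(2 / (M - 1))
    expect_lt(abs(st$mean - oracle$mean[k]), 3 * se_mean * 3) # 3 SE with slack
    expect_lt(abs(st$var - oracle$var[k]), 3 * se_var * 3)
  }
})

test_that("filter runs are deterministic under a fixed seed", {
  g <- small_grid(n_age = 60, n_steps = 10)
  run_once <- function() {
    run_toy_twin(seed = 123, M = 30, grid = g, update_every = 5)
  }
  f1 <- run_once(); f2 <- run_once()
  expect_identical(f1$param_mean, f2$param_mean)
  expect_identical(f1$ensemble$X, f2$ensemble$X)
})

test_that("without observations the filter integrates the model freely", {
  g <- age_time_grid(n_age = 80, delta_t = 0.01, n_steps = 100)
  model <- toy_filter_model(g)
  p <- toy_ref()
  x0 <- c(rep(0, 80), log(p$mu), log(p$lam))
  ens <- init_ensemble(x0, rep(0, 82), 2, model$layout, seed = 5)
  fit <- run_enkf(ens, model$rate_fn, model$h,
                  obs_times = numeric(0), obs_z = NULL,
                  t0 = 0, delta_t = 0.01, n_steps = 100,
                  Q = process_noise("none"), R = 1e-4)
  ages <- grid_ages(g)
  truth <- toy_density(ages, 1, p)
  expect_lt(max(abs(fit$ensemble$X[1:80, 1] - truth)), 5e-3) # Euler at dt = 0.01
})

test_that("off-grid observation times are rejected", {
  g <- small_grid(n_age = 20, n_steps = 10)
  model <- toy_filter_model(g)
  ens <- init_ensemble(rep(0, 22), rep(0, 22), 2, model$layout, seed = 1)
  expect_error(
    run_enkf(ens, model$rate_fn, model$h, obs_times = 0.55,
             obs_z = matrix(0, 20, 1), delta_t = 0.1, n_steps = 10),
    "not on the step grid")
})

test_that("posterior parameter trajectories stay positive", {
  fit <- run_toy_twin(seed = 3, M = 40, grid = small_grid(n_age = 60, n_steps = 20),
                      update_every = 5)
  expect_true(all(fit$param_mean > 0))
  expect_true(all(fit$param_sd >= 0))
})
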