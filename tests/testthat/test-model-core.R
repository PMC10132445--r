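test_that("closed-form toy density matches quadrature of the formal solution", {
  p <- toy_ref()
  spec <- toy_spec(p)
  for (pt in list(c(30, 10), c(5, 2), c(80, 9.5), c(2, 7), c(0.5, 0.2))) {
    quad <- characteristic_solution(spec, pt[1], pt[2])
    closed <- toy_density(pt[1], pt[2], p)
    expect_lt(abs(closed - quad) / max(quad, 1e-300), 1e-8)
  }
})

test_that("toy density honours initial and boundary conditions", {
  p <- toy_ref()
  expect_equal(toy_density(5, 0, p), 0)        # rho(a) = 0
  expect_equal(toy_density(c(1, 30, 119), 0, p), c(0, 0, 0))
  expect_lt(toy_density(1e-12, 10, p), 1e-12)  # g(t) = 0 at age 0
  expect_true(all(toy_density(seq(0, 120, by = 1), 7.3, p) >= 0))
})

test_that("the two characteristic branches join continuously at a = t", {
  set.seed(11)
  for (i in 1:100) {
    tt <- runif(1, 0.1, 40)
    mu <- runif(1, 0.01, 0.5)
    lam <- runif(1, 0.01, 0.5)
    if (abs(lam - mu) < 1e-4) next
    p <- toy_params(mu, lam)
    # older-characteristic branch at a = t vs the stationary branch there
    expect_lt(abs(toy_density(tt, tt, p) - toy_steady_state(tt, p)), 1e-12)
  }
})

test_that("near-degenerate lam ~ mu evaluates through the series branch", {
  # straddle the branch threshold; values must agree smoothly
  p_raw <- toy_params(0.1, 0.1 + 2e-6)     # raw formula
  p_ser <- toy_params(0.1, 0.1 + 0.9e-6)   # series branch
  for (pt in list(c(10, 4), c(3, 8), c(50, 20))) {
    v1 <- toy_density(pt[1], pt[2], p_raw)
    v2 <- toy_density(pt[1], pt[2], p_ser)
    expect_lt(abs(v1 - v2) / v2, 1e-3)
    expect_true(is.finite(v1) && v1 >= 0)
  }
  # exactly equal rates: series limit only
  p_eq <- toy_params(0.1, 0.1 + 1e-12)
  expect_true(is.finite(toy_density(10, 4, p_eq)))
  expect_gt(toy_density(10, 4, p_eq), 0)
})

test_that("toy rate of change matches the finite-difference oracle", {
  p <- toy_ref()
  h <- 1e-5
  for (pt in list(c(10, 5), c(40, 3), c(25, 24))) {
    fd <- (toy_density(pt[1], pt[2] + h, p) -
             toy_density(pt[1], pt[2] - h, p)) / (2 * h)
    expect_equal(toy_rate_of_change(pt[1], pt[2], p), fd, tolerance = 1e-6)
  }
  expect_equal(toy_rate_of_change(3, 3, p), 0)   # (a - t) prefactor
  expect_equal(toy_rate_of_change(2, 5, p), 0)   # stationary branch a < t
  expect_equal(toy_rate_of_change(10, 5, p), 5 * exp(-0.2 * 5 - 0.08 * 5))
})

test_that("peak trajectory tracks the grid argmax and its small-t limit", {
  p <- toy_ref()
  expect_equal(peak_trajectory(0, p), 1 / p$lam) # argmax of the influx profile
  a_grid <- seq(0, 60, by = 0.01)
  for (tt in c(2, 5, 9)) {
    amax_grid <- a_grid[which.max(toy_density(a_grid, tt, p))]
    expect_lt(abs(peak_trajectory(tt, p) - amax_grid), 0.01)
  }
  traj <- peak_trajectory(1:10, p)
  expect_true(all(traj > 1:10))                  # ahead of the a = t seam
  expect_true(all(diff(traj) > 0))               # ages forward in time
})

test_that("steady state equals the density once t exceeds a", {
  p <- toy_ref()
  expect_equal(toy_steady_state(0, p), 0)
  expect_equal(toy_steady_state(20, p), toy_density(20, 100, p))
  expect_equal(toy_steady_state(20, p), toy_density(20, 20.01, p))
  expect_lt(toy_steady_state(700, p), 1e-12)     # decays at old ages
})

test_that("pure transport decays the initial condition along characteristics", {
  mu0 <- 0.3
  spec <- general_model_spec(
    mortality = function(a, t) rep_len(mu0, length(a)),
    influx = function(a, t) 0 * a,
    initial_density = function(a) exp(-a))
  # rho(a - t) exp(-mu0 t) exactly
  expect_equal(characteristic_solution(spec, 10, 2), exp(-8) * exp(-2 * mu0),
               tolerance = 1e-9)
  # age-dependent mortality: integral along the characteristic is closed-form
  spec2 <- general_model_spec(
    mortality = function(a, t) 0.05 + 0.01 * a,
    influx = function(a, t) 0 * a,
    initial_density = function(a) exp(-a))
  a <- 10; tt <- 2
  mu_int <- 0.05 * tt + 0.01 * ((a - tt) * tt + tt^2 / 2)
  expect_equal(characteristic_solution(spec2, a, tt), exp(-(a - tt)) * exp(-mu_int),
               tolerance = 1e-9)
})

test_that("young-age branch accumulates influx from the zero boundary only", {
  # constant influx and mortality: n(a < t) = p0 (1 - exp(-mu a)) / mu
  p0 <- 2; mu0 <- 0.4
  spec <- general_model_spec(
    mortality = function(a, t) rep_len(mu0, length(a)),
    influx = function(a, t) rep_len(p0, length(a)))
  expect_equal(characteristic_solution(spec, 0.5, 2),
               p0 * (1 - exp(-mu0 * 0.5)) / mu0, tolerance = 1e-9)
})

test_that("invalid inputs are rejected", {
  expect_error(toy_params(-0.1, 0.2), "> 0")
  expect_error(toy_density(-1, 2, toy_ref()), ">= 0")
  expect_error(characteristic_solution(toy_spec(toy_ref()), 5, -1), ">= t0")
})
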