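test_that("addiction rate is a normalized gamma mixture", {
  p <- sud_params()
  total <- integrate(function(x) addiction_rate(x, p), 0, Inf)$value
  expect_equal(total, p$r0, tolerance = 1e-8)
  # mean entry age of the default configuration
  mean_age <- integrate(function(x) x * addiction_rate(x, p), 0, Inf)$value / p$r0
  expect_equal(mean_age, 45, tolerance = 1e-6)
  # pointwise value against an independent pdf evaluation
  expect_equal(addiction_rate(45, sud_params(r0 = 0.04)),
               0.04 * dgamma(45, shape = 15, rate = 1 / 3),
               tolerance = 1e-12)
  # component swap symmetry
  p_a <- sud_params(alpha1 = 12, beta1 = 0.4, alpha2 = 18, beta2 = 0.3)
  p_b <- sud_params(alpha1 = 18, beta1 = 0.3, alpha2 = 12, beta2 = 0.4)
  aa <- seq(0, 100, by = 2.5)
  expect_equal(addiction_rate(aa, p_a), addiction_rate(aa, p_b))
})

test_that("closed-form addiction integral matches quadrature", {
  p <- sud_params()
  expect_equal(cumulative_addiction_integral(0, Inf, p), p$r0)
  expect_equal(cumulative_addiction_integral(17, 17, p), 0)
  quad <- integrate(function(x) addiction_rate(x, p), 10, 50,
                    rel.tol = 1e-12)$value
  expect_equal(cumulative_addiction_integral(10, 50, p), quad,
               tolerance = 1e-10)
  expect_error(cumulative_addiction_integral(5, 2, p), "a_lo <= a_hi")
})

test_that("SUD density solves the along-characteristic ODE", {
  skip_if_not_installed("deSolve")
  p <- sud_params()
  pop <- population_model()
  for (pt in list(c(40, 10), c(25, 15), c(8, 20))) {
    a <- pt[1]; tt <- pt[2]
    lo <- max(a - tt, 0)
    f <- function(u, y, parms) {
      r <- addiction_rate(u, p)
      N <- population_at(pop, 1998 + (u - a + tt))
      list(-(p$mu + r) * y + r * N)
    }
    sol <- deSolve::ode(c(n = 0), seq(lo, a, length.out = 501), f, NULL,
                        method = "ode45", atol = 1e-6, rtol = 1e-10)
    oracle <- unname(sol[nrow(sol), 2])
    expect_equal(sud_density(a, tt, p), oracle, tolerance = 1e-7)
  }
})

test_that("SUD density boundary cases vanish", {
  p <- sud_params()
  expect_equal(sud_density(c(5, 40, 100), 0, p), c(0, 0, 0))
  p0 <- sud_params(r0 = 0)
  expect_equal(sud_density(c(5, 40), 12, p0), c(0, 0))
  expect_equal(sud_density(0, 12, p), 0)
})

test_that("SUD rate of change matches finite differences of the density", {
  p <- sud_params()
  h <- 1e-4
  set.seed(5)
  pts <- cbind(a = runif(8, 1, 110), t = runif(8, 0.5, 22))
  for (i in seq_len(nrow(pts))) {
    a <- pts[i, 1]; tt <- pts[i, 2]
    fd <- (sud_density(a, tt + h, p) - sud_density(a, tt - h, p)) / (2 * h)
    rc <- sud_rate_of_change(a, tt, p)
    expect_equal(rc, fd, tolerance = 1e-6)
  }
})

test_that("integrating the rate in time reproduces the density", {
  p <- sud_params()
  dt <- 0.01
  for (a in c(20, 47.5, 80)) {
    n <- 0
    for (k in 0:499) n <- n + dt * sud_rate_of_change(a, k * dt, p)
    expect_equal(n, sud_density(a, 5, p), tolerance = 5e-3)
  }
})

test_that("constant-rate limit recovers the textbook closed form", {
  # with r(a) = r and N constant the young-age branch is
  # n = r N (1 - exp(-(mu + r) a)) / (mu + r)
  r <- 0.02; mu <- 0.001; N <- 1e6
  spec <- general_model_spec(
    mortality = function(a, t) rep_len(mu + r, length(a)),
    influx = function(a, t) rep_len(r * N, length(a)))
  a <- 30
  expect_equal(characteristic_solution(spec, a, 40),
               r * N * (1 - exp(-(mu + r) * a)) / (mu + r),
               tolerance = 1e-9)
})

test_that("vectorized grid profile agrees with pointwise quadrature", {
  p <- sud_params()
  g <- small_grid(n_age = 1000)
  prof <- sud_density_profile(g, 10, p)
  ages <- grid_ages(g)
  idx <- c(100, 300, 417, 600, 900)
  ref <- sud_density(ages[idx], 10, p)
  expect_equal(prof[idx], ref, tolerance = 1e-4)
  expect_true(all(prof >= 0))
})

test_that("death accumulation is a clipped rectangle rule", {
  g <- small_grid()
  D0 <- cumulative_death_field(g, 0, rep(0, g$n_age))
  nf <- density_field(g, 0, rep(2, g$n_age))
  # constant density: increment mu n dt per cell
  D1 <- accumulate_deaths(D0, nf, mu = 0.5, delta_t = 0.1)
  expect_equal(D1$values, rep(0.5 * 2 * 0.1, g$n_age))
  expect_equal(D1$t, 0.1)
  # zero density or zero mortality: unchanged
  expect_equal(accumulate_deaths(D0, density_field(g, 0, rep(0, g$n_age)),
                                 0.5, 0.1)$values, rep(0, g$n_age))
  expect_equal(accumulate_deaths(D0, nf, 0, 0.1)$values, rep(0, g$n_age))
  # negative density clipped for the increment
  neg <- density_field(g, 0, rep(-1, g$n_age))
  expect_equal(accumulate_deaths(D0, neg, 0.5, 0.1)$values, rep(0, g$n_age))
  # monotone over repeated steps
  D <- D0
  for (k in 1:5) D <- accumulate_deaths(D, nf, 0.5, 0.1)
  expect_true(all(diff(rbind(D1$values, D$values)) >= 0))
})
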