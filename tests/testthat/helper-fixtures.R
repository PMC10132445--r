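# Shared fixtures: small grids and parameter sets used across test files.

toy_ref <- function() toy_params(mu = 0.08, lam = 0.2)

small_grid <- function(n_age = 100, delta_t = 0.1, n_steps = 20) {
  age_time_grid(n_age = n_age, a_max = 120, delta_t = delta_t,
                n_steps = n_steps)
}

# brute-force trapezoid integral of grid values over [0, 120] with the same
# constant-extrapolation stub convention as the coarse-graining matrix
trapz_total <- function(grid, values) {
  a <- grid_ages(grid)
  n <- length(a)
  sum(diff(a) * (values[-1] + values[-n]) / 2) +
    (grid$a_max - a[n]) * values[n]
}

# exact discrete Kalman recursion for the scalar linear-Gaussian system
# x_{k+1} = a x_k + w (var q), z = x + v (var r); the independent oracle for
# the ensemble filter
scalar_kf <- function(z, a, q, r, m0, p0) {
  n <- length(z)
  m <- numeric(n); p <- numeric(n)
  mc <- m0; pc <- p0
  for (k in seq_len(n)) {
    mp <- a * mc; pp <- a^2 * pc + q
    K <- pp / (pp + r)
    mc <- mp + K * (z[k] - mp)
    pc <- (1 - K) * pp
    m[k] <- mc; p[k] <- pc
  }
  list(mean = m, var = p)
}
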