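#' State layout, rate and measurement functions for the toy twin experiment
#'
#' The augmented state is \code{[n(a_0), ..., n(a_{Na-1}), log mu, log lam]}.
#' The rate function evaluates each member's closed-form density derivative
#' at that member's own (exponentiated) parameters; the measurement is the
#' identity on the density block (every age cell observed).
#'
#' @param grid an \code{\link{age_time_grid}}.
#' @return list with \code{layout}, \code{rate_fn}, \code{h}.
#' @export
toy_filter_model <- function(grid) {
  ages <- grid_ages(grid)
  n_a <- grid$n_age
  layout <- state_layout(n_a, 0L, c("mu", "lam"), log_params = TRUE)
  rate_fn <- function(X, t) {
    mu <- exp(X[n_a + 1L, ])
    lam <- exp(X[n_a + 2L, ])
    d <- ages - t
    up <- d >= 0
    F <- matrix(0, nrow(X), ncol(X))
    if (any(up)) {
      dd <- d[up]
      # (a - t) exp(-lam (a - t) - mu t), member-wise columns
      F[which(up), ] <- dd * exp(-outer(dd, lam) -
                                   matrix(t * mu, sum(up), length(mu), byrow = TRUE))
    }
    F
  }
  h <- function(X) X[seq_len(n_a), , drop = FALSE]
  list(layout = layout, rate_fn = rate_fn, h = h)
}

#' State layout, rate and measurement functions for the SUD pipeline
#'
#' The augmented state stacks the density block, the cumulative-death block
#' and the six log-transformed parameters
#' \code{(mu, r0, alpha1, beta1, alpha2, beta2)}. The density rate is the
#' state-independent closed-form derivative of the characteristic solution,
#' evaluated per member with running trapezoid integrals of that member's
#' influx profile on the age grid; the death-block rate is \code{mu * n}
#' (negative densities clipped). The measurement coarse-grains the death
#' block onto the 22 data bins and divides by \code{death_scale}.
#'
#' @param grid an \code{\link{age_time_grid}}.
#' @param pop a \code{\link{population_model}}.
#' @param start_year calendar year of model time 0.
#' @param schema an \code{\link{age_bin_schema}}.
#' @param death_scale divisor applied to modelled and observed deaths so the
#'   filter works with O(1) numbers (default 1e3).
#' @return list with \code{layout}, \code{rate_fn}, \code{h}, and the
#'   coarse-graining matrix \code{W}.
#' @export
sud_filter_model <- function(grid, pop = population_model(),
                             start_year = 1998, schema = cdc_age_bins(),
                             death_scale = 1e3) {
  ages <- grid_ages(grid)
  n_a <- grid$n_age
  h_a <- grid$delta_a
  layout <- state_layout(n_a, n_a,
                         c("mu", "r0", "alpha1", "beta1", "alpha2", "beta2"),
                         log_params = TRUE)
  W <- coarse_grain_matrix(grid, schema)
  idx_n <- layout$idx_density
  idx_d <- layout$idx_deaths
  idx_p <- layout$idx_params
  dN <- pop$delta_N
  N_start <- population_at(pop, start_year)
  log_ages <- suppressWarnings(log(ages)) # -Inf at a = 0, handled below
  # gamma mixture pdf at a set of ages for all members at once (ages x M);
  # built from the log-density so one matrix exp serves the whole ensemble
  gamma_mix <- function(av, log_av, r0, a1, b1, a2, b2) {
    nr <- length(av)
    E1 <- exp(outer(log_av, a1 - 1) - outer(av, b1) +
              matrix(a1 * log(b1) - lgamma(a1), nr, length(a1), byrow = TRUE))
    E2 <- exp(outer(log_av, a2 - 1) - outer(av, b2) +
              matrix(a2 * log(b2) - lgamma(a2), nr, length(a2), byrow = TRUE))
    E <- E1 + E2
    E[!is.finite(E)] <- 0          # age-0 column under shape < 1
    E * matrix(r0 / 2, nr, length(r0), byrow = TRUE)
  }
  # columnwise running trapezoid integral on the uniform age grid; the
  # columnwise cumsum is one full-vector cumsum with per-column offsets
  # subtracted (cheaper than apply for wide ensembles)
  col_cumtrapz <- function(Y) {
    n <- nrow(Y); M <- ncol(Y)
    Z <- rbind(0, (Y[-1, , drop = FALSE] + Y[-n, , drop = FALSE]) / 2 * h_a)
    V <- matrix(cumsum(Z), n, M)
    V - matrix(c(0, V[n, -M]), n, M, byrow = TRUE)
  }
  rate_fn <- function(X, t) {
    M <- ncol(X)
    F <- matrix(0, nrow(X), M)
    P <- exp(X[idx_p, , drop = FALSE])
    mu <- P[1, ]; r0 <- P[2, ]
    # shifted-grid interpolation: a_j - t has a constant fractional offset
    # on a uniform grid, shared by all members
    shift_pos <- (ages - t - grid$a0) / h_a
    up <- shift_pos >= 0            # ages with a >= t
    idx0 <- pmin(pmax(floor(shift_pos), 0), n_a - 1L)
    frac <- shift_pos - floor(shift_pos)
    lo_i <- as.integer(idx0) + 1L
    hi_i <- pmin(lo_i + 1L, n_a)
    a_shift <- pmax(ages - t, 0)
    r <- gamma_mix(ages, log_ages, r0, P[3, ], P[4, ], P[5, ], P[6, ])
    R <- col_cumtrapz(r)
    w <- exp(outer(ages, mu) + R)   # exp(mu a + R(a)); damping factor is 1/w
    G <- col_cumtrapz(r * w)
    interp <- function(V) {
      out <- (1 - frac) * V[lo_i, , drop = FALSE] +
        frac * V[hi_i, , drop = FALSE]
      out[!up, ] <- 0               # lower limit clamps to age 0 where a < t
      out
    }
    R_lo <- interp(R)
    G_lo <- interp(G)
    rate_n <- dN * (G - G_lo) / w
    if (any(up)) {
      r_shift <- gamma_mix(a_shift, suppressWarnings(log(a_shift)),
                           r0, P[3, ], P[4, ], P[5, ], P[6, ])
      bdry <- r_shift * N_start *
        exp(R_lo - R - outer(rep(t, n_a), mu))
      rate_n[up, ] <- rate_n[up, ] + bdry[up, , drop = FALSE]
    }
    F[idx_n, ] <- rate_n
    F[idx_d, ] <- pmax(X[idx_n, , drop = FALSE], 0) *
      matrix(mu, n_a, M, byrow = TRUE)
    F
  }
  h <- function(X) (W %*% X[idx_d, , drop = FALSE]) / death_scale
  list(layout = layout, rate_fn = rate_fn, h = h, W = W)
}

#' Run the toy twin experiment
#'
#' Generates noisy synthetic observations of the toy density at known
#' parameters and runs the augmented EnKF with the reference settings:
#' ages [0, 120] in 1000 cells, \code{delta_t = 0.1} yr to \code{t = 10},
#' \code{M = 500} members, process noise of variance 1e-4,
#' observation noise variance 1e-4 on every age cell, initial state
#' \code{[1e-5, ..., 1e-5]} with parameter guesses 0.1/yr (stored as logs),
#' prior variances 0.5 (density) and 1 (log parameters), and an update every
#' 5 forecast steps.
#'
#' @param seed integer RNG seed (one stream drives ensemble initialization,
#'   observation noise and filter noise draws).
#' @param true_params data-generating \code{\link{toy_params}}.
#' @param M ensemble size.
#' @param grid the \code{\link{age_time_grid}}.
#' @param update_every number of forecast steps between updates.
#' @param obs_noise_var observation noise variance added to the density.
#' @param R_var observation noise variance assumed by the filter; defaults
#'   to \code{obs_noise_var} (kept positive so the innovation covariance
#'   stays invertible even for noise-free data).
#' @param x0_density,x0_param_guess,P0_density,P0_param initial mean and
#'   prior variances of the density block and (log) parameter block.
#' @param Q process-noise specification; the default is independent noise of
#'   variance 1e-4 on every state entry. (A fully correlated rank-one
#'   variant of the same variance, \code{process_noise("ones", 1e-2)}, is
#'   available but cannot explore the two parameters differentially and is
#'   not recommended; see the vignette.)
#' @return the \code{\link{run_enkf}} fit, with the observation list in
#'   \code{$observations} and truth in \code{$true_params}.
#' @export
run_toy_twin <- function(seed = 1,
                         true_params = toy_params(mu = 0.08, lam = 0.2),
                         M = 500,
                         grid = age_time_grid(n_age = 1000, delta_t = 0.1,
                                              n_steps = 100),
                         update_every = 5,
                         obs_noise_var = 1e-4, R_var = NULL,
                         x0_density = 1e-5, x0_param_guess = 0.1,
                         P0_density = 0.5, P0_param = 1,
                         Q = process_noise("diag", 1e-2)) {
  model <- toy_filter_model(grid)
  set.seed(as.integer(seed))
  obs <- generate_toy_observations(
    twin_experiment_spec(true_params, obs_noise_var,
                         schedule = grid_times(grid)[
                           1 + seq(update_every, grid$n_steps, by = update_every)]),
    grid)
  x0 <- c(rep(x0_density, grid$n_age),
          transform_params(rep(x0_param_guess, 2), model$layout))
  P0 <- c(rep(P0_density, grid$n_age), rep(P0_param, 2))
  ens <- init_ensemble(x0, P0, M, model$layout)
  fit <- run_enkf(ens, model$rate_fn, model$h,
                  obs_times = obs$times, obs_z = obs$z,
                  t0 = grid$t0, delta_t = grid$delta_t, n_steps = grid$n_steps,
                  Q = Q, R = if (is.null(R_var)) max(obs_noise_var, 1e-8) else R_var,
                  record_predictions = FALSE)
  fit$observations <- obs
  fit$true_params <- true_params
  fit
}

#' Earliest time after which a parameter estimate stays within tolerance
#'
#' Scans a parameter trajectory and returns the earliest time \code{t*} such
#' that the relative error against the reference value stays below
#' \code{tol} for all recorded times \code{>= t*} (Inf if never).
#'
#' @param times recorded times.
#' @param est estimate trajectory.
#' @param truth reference value.
#' @param tol relative tolerance (default 0.1).
#' @return a time in years (possibly Inf).
#' @export
convergence_time <- function(times, est, truth, tol = 0.1) {
  ok <- abs(est - truth) / abs(truth) < tol
  if (!any(ok)) return(Inf)
  bad <- which(!ok)
  if (!length(bad)) return(times[1])
  if (max(bad) == length(ok)) return(Inf)
  times[max(bad) + 1L]
}
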