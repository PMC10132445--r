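#' Twin-experiment specification
#'
#' Bundles the data-generating ("true") parameters, the observation noise
#' level, the observation schedule and an optional seed for the noise draws.
#' Twin experiments generate synthetic observations from the model at known
#' parameters and check that the filter recovers them.
#'
#' @param true_params a \code{\link{toy_params}} or \code{\link{sud_params}}
#'   object.
#' @param obs_noise_var observation noise variance (density units squared for
#'   the toy model; death counts for the SUD generator use a standard
#'   deviation in deaths, see \code{\link{generate_cdc_like_counts}}).
#' @param schedule observation times in years.
#' @param seed optional integer seed; if \code{NULL} the current RNG stream
#'   is used.
#' @return an object of class \code{twin_experiment_spec}.
#' @export
twin_experiment_spec <- function(true_params, obs_noise_var, schedule,
                                 seed = NULL) {
  stopifnot(obs_noise_var >= 0, length(schedule) >= 1)
  structure(list(true_params = true_params, obs_noise_var = obs_noise_var,
                 schedule = as.numeric(schedule), seed = seed),
            class = "twin_experiment_spec")
}

#' Synthetic observations for the toy twin experiment
#'
#' Evaluates the closed-form toy density on the age grid at the scheduled
#' times and adds i.i.d. Gaussian noise of the requested variance to every
#' age cell.
#'
#' @param spec a \code{\link{twin_experiment_spec}} with toy parameters.
#' @param grid an \code{\link{age_time_grid}}.
#' @return list with \code{times}, the noisy observation matrix \code{z}
#'   (\code{n_age} x number of times) and the noise-free \code{truth}.
#' @export
generate_toy_observations <- function(spec, grid) {
  stopifnot(inherits(spec, "twin_experiment_spec"),
            inherits(spec$true_params, "toy_params"))
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  ages <- grid_ages(grid)
  truth <- vapply(spec$schedule,
                  function(tt) toy_density(ages, tt, spec$true_params),
                  numeric(grid$n_age))
  noise <- if (spec$obs_noise_var > 0) {
    matrix(stats::rnorm(length(truth), sd = sqrt(spec$obs_noise_var)),
           nrow = nrow(truth))
  } else 0
  list(times = spec$schedule, z = truth + noise, truth = truth)
}

#' Cumulative death profiles of the SUD model over time
#'
#' Integrates \code{mu * n(a, t')} in time on the model grid (trapezoid rule
#' on a fine time step) to obtain the cumulative-death field
#' \code{Dtil(a_j, t)} at each requested time.
#'
#' @param grid an \code{\link{age_time_grid}}.
#' @param times output times (years since start), ascending, >= 0.
#' @param params a \code{\link{sud_params}}.
#' @param pop a \code{\link{population_model}}.
#' @param start_year calendar year of model time 0.
#' @param dt_int internal time step of the death integral.
#' @return matrix \code{n_age} x \code{length(times)} of cumulative deaths
#'   per year of age.
#' @export
sud_cumulative_deaths <- function(grid, times, params,
                                  pop = population_model(), start_year = 1998,
                                  dt_int = 0.05) {
  stopifnot(all(diff(times) > 0), all(times >= 0))
  t_max <- max(times)
  t_fine <- seq(0, t_max, by = dt_int)
  if (t_fine[length(t_fine)] < t_max) t_fine <- c(t_fine, t_max)
  mu <- params$mu
  D <- matrix(0, grid$n_age, length(times))
  acc <- numeric(grid$n_age)
  prev_rate <- mu * sud_density_profile(grid, 0, params, pop, start_year)
  out_j <- 1L
  tol <- 1e-9
  while (out_j <= length(times) && abs(times[out_j]) < tol) {
    D[, out_j] <- acc; out_j <- out_j + 1L
  }
  for (k in 2:length(t_fine)) {
    rate <- mu * sud_density_profile(grid, t_fine[k], params, pop, start_year)
    acc <- acc + (t_fine[k] - t_fine[k - 1]) * (rate + prev_rate) / 2
    prev_rate <- rate
    while (out_j <= length(times) && t_fine[k] >= times[out_j] - tol) {
      D[, out_j] <- acc
      out_j <- out_j + 1L
    }
  }
  D
}

#' Synthetic CDC WONDER style annual death counts
#'
#' Runs the SUD model forward from a zero initial density, coarse-grains the
#' cumulative deaths onto the 22 data bins at the start of every year,
#' differences consecutive years to annual counts, adds Gaussian observation
#' noise and rounds to non-negative integers. The result emulates a WONDER
#' multiple-cause-of-death export on the model's own terms and feeds the
#' assimilation pipeline in twin experiments.
#'
#' @param params data-generating \code{\link{sud_params}}.
#' @param years calendar years of the annual counts (first year is the
#'   simulation start year: its count covers deaths during that year).
#' @param schema an \code{\link{age_bin_schema}}.
#' @param grid the model \code{\link{age_time_grid}} (age discretization
#'   only; time stepping is internal).
#' @param pop a \code{\link{population_model}}.
#' @param noise_sd observation noise standard deviation in deaths (the
#'   measurement scale of the assimilation: about 10-100 deaths).
#' @param seed optional integer seed for the noise draws.
#' @return a \code{\link{mortality_table}} of annual counts; the noise-free
#'   counts are attached as attribute \code{"truth"}.
#' @export
generate_cdc_like_counts <- function(params, years = 1998:2017,
                                     schema = cdc_age_bins(),
                                     grid = age_time_grid(n_age = 1000),
                                     pop = population_model(),
                                     noise_sd = 10, seed = NULL) {
  stopifnot(inherits(params, "sud_params"), length(years) >= 1,
            all(diff(years) == 1))
  if (!is.null(seed)) set.seed(as.integer(seed))
  start_year <- years[1]
  W <- coarse_grain_matrix(grid, schema)
  t_edges <- c(0, years + 1 - start_year) # year boundaries in model time
  D <- sud_cumulative_deaths(grid, t_edges, params, pop, start_year)
  cum_bins <- t(W %*% D)                  # (length(years)+1) x 22
  annual_true <- diff(cum_bins)
  noise <- if (noise_sd > 0) {
    matrix(stats::rnorm(length(annual_true), sd = noise_sd),
           nrow = nrow(annual_true))
  } else 0
  counts <- pmax(round(annual_true + noise), 0)
  tab <- mortality_table(years, counts, schema = schema)
  attr(tab, "truth") <- annual_true
  tab
}
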