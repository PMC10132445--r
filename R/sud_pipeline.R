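#' Assimilate age-binned annual death counts into the SUD model
#'
#' Runs the augmented EnKF on a \code{\link{mortality_table}}: the state
#' stacks the density and cumulative-death blocks plus the six
#' log-transformed parameters; observations are the cumulative per-bin death
#' counts (running sums of the annual counts, divided by the death scale),
#' assimilated at the beginning of the year after the counts accrue. After
#' the last data year the filter keeps forecasting for \code{horizon} more
#' years, recording the predicted observation mean and spread at every step.
#'
#' @param table a \code{\link{mortality_table}} whose first year is the
#'   simulation start year.
#' @param M ensemble size.
#' @param grid the model \code{\link{age_time_grid}} (age part; the time
#'   part is derived from the data span and \code{delta_t}).
#' @param pop a \code{\link{population_model}}.
#' @param init_params initial parameter guesses (a \code{\link{sud_params}};
#'   default: the reference configuration with gamma means at 45 years).
#' @param P0_state initial variance of the density and death entries.
#' @param P0_param initial variance of the log-parameter entries.
#' @param Q process noise (independent entries, standard deviation 1e-2
#'   by default).
#' @param R_var observation noise variance on the scaled death counts.
#' @param death_scale divisor bringing death counts to O(1).
#' @param delta_t forecast step in years.
#' @param horizon extra forecast years beyond the last data year.
#' @param seed integer RNG seed.
#' @return an \code{enkf_fit} (see \code{\link{run_enkf}}) with fields
#'   \code{years}, \code{schema}, \code{death_scale}, \code{start_year} and
#'   \code{cum_obs} added.
#' @export
run_sud_assimilation <- function(table, M = 1e4,
                                 grid = age_time_grid(n_age = 1000),
                                 pop = population_model(),
                                 init_params = sud_params(),
                                 P0_state = 1e-4, P0_param = 1e-2,
                                 Q = process_noise("diag", 1e-2),
                                 R_var = 1e-4, death_scale = 1e3,
                                 delta_t = 0.1, horizon = 0, seed = 1) {
  stopifnot(inherits(table, "mortality_table"))
  start_year <- table$years[1]
  n_years <- length(table$years)
  model <- sud_filter_model(grid, pop, start_year, table$schema, death_scale)
  cum_obs <- to_cumulative(table)
  obs_times <- seq_len(n_years)        # year-Y data assimilated at t = Y+1-start
  obs_z <- t(cum_obs) / death_scale
  steps_per_year <- round(1 / delta_t)
  n_steps <- (n_years + horizon) * steps_per_year
  set.seed(as.integer(seed))
  x0 <- c(rep(0, grid$n_age), rep(0, grid$n_age),
          transform_params(unlist(init_params, use.names = FALSE),
                           model$layout))
  P0 <- c(rep(P0_state, 2 * grid$n_age), rep(P0_param, 6))
  ens <- init_ensemble(x0, P0, M, model$layout)
  fit <- run_enkf(ens, model$rate_fn, model$h,
                  obs_times = obs_times, obs_z = obs_z,
                  t0 = 0, delta_t = delta_t, n_steps = n_steps,
                  Q = Q, R = R_var,
                  record_predictions = TRUE, forecast_record = horizon > 0)
  fit$years <- table$years
  fit$schema <- table$schema
  fit$death_scale <- death_scale
  fit$start_year <- start_year
  fit$cum_obs <- cum_obs
  fit
}

#' Annual predicted-versus-observed death counts from an assimilation fit
#'
#' For each data year, the prediction is the filter's predicted cumulative
#' count immediately before that year's data was assimilated, minus the
#' observed cumulative count through the previous year; it therefore uses
#' only observations up to the previous year. The ensemble spread of the
#' predicted cumulative count gives the uncertainty band.
#'
#' @param fit result of \code{\link{run_sud_assimilation}}.
#' @param sd_mult half-width of the reported band in ensemble standard
#'   deviations (3 for assimilation-period reporting).
#' @return data frame with year, age-group label, observed and predicted
#'   annual deaths and the band half-width (all in deaths).
#' @export
annual_predictions <- function(fit, sd_mult = 3) {
  sc <- fit$death_scale
  years <- fit$years
  out <- NULL
  for (i in seq_along(years)) {
    tt <- i # model time of the update for year years[i]
    j <- which(abs(fit$pred_times - tt) < 1e-9)
    if (length(j) != 1) next
    prev_cum <- if (i == 1) rep(0, 22) else fit$cum_obs[i - 1, ]
    pred_annual <- fit$pred_mean[, j] * sc - prev_cum
    out <- rbind(out, data.frame(
      year = years[i],
      age_group = fit$schema$labels,
      observed = fit$cum_obs[i, ] - prev_cum,
      predicted = pred_annual,
      band = sd_mult * fit$pred_sd[, j] * sc,
      row.names = NULL))
  }
  out
}

#' Forecast annual death counts beyond the last data year
#'
#' Differences the predicted cumulative counts at consecutive year
#' boundaries in the pure-forecast segment of an assimilation run (requires
#' \code{horizon > 0} in \code{\link{run_sud_assimilation}}). Bands are
#' \code{sd_mult} ensemble standard deviations of the predicted cumulative
#' count at the end of the forecast year.
#'
#' @param fit result of \code{\link{run_sud_assimilation}} with a horizon.
#' @param sd_mult band half-width in ensemble standard deviations
#'   (2 for out-of-sample forecasts).
#' @return data frame with year, age-group label, forecast annual deaths and
#'   band half-width.
#' @export
forecast_annual <- function(fit, sd_mult = 2) {
  sc <- fit$death_scale
  n_years <- length(fit$years)
  last_t <- n_years
  horizon_times <- fit$pred_times[fit$pred_times > last_t + 1e-9]
  year_ends <- horizon_times[abs(horizon_times - round(horizon_times)) < 1e-9]
  if (!length(year_ends))
    stop("forecast_annual: fit contains no forecast segment (set horizon > 0)")
  prev_cum <- fit$cum_obs[n_years, ]
  out <- NULL
  for (te in year_ends) {
    j <- which(abs(fit$pred_times - te) < 1e-9)
    pred_cum <- fit$pred_mean[, j] * sc
    out <- rbind(out, data.frame(
      year = fit$start_year + round(te) - 1L,
      age_group = fit$schema$labels,
      forecast = pred_cum - prev_cum,
      band = sd_mult * fit$pred_sd[, j] * sc,
      row.names = NULL))
    prev_cum <- pred_cum
  }
  out
}

#' Final parameter estimates of an EnKF fit
#'
#' Ensemble means of the natural-scale parameters at the last recorded step,
#' with their ensemble standard deviations.
#'
#' @param fit an \code{enkf_fit}.
#' @return data frame with parameter, estimate and sd columns.
#' @export
final_estimates <- function(fit) {
  k <- nrow(fit$param_mean)
  data.frame(parameter = colnames(fit$param_mean),
             estimate = unname(fit$param_mean[k, ]),
             sd = unname(fit$param_sd[k, ]),
             row.names = NULL)
}
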