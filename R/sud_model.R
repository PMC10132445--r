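#' Parameters of the substance-use-disorder (SUD) mortality model
#'
#' Overdose mortality rate \code{mu} plus the gamma-mixture addiction influx:
#' \code{r(a) = (r0 / 2) [f1(a; alpha1, beta1) + f2(a; alpha2, beta2)]}, where
#' \code{f_i} is the gamma density with shape \code{alpha_i} and rate
#' \code{beta_i}. The two components capture a double-peaked age profile of
#' new addictions; \code{r0} is the base modulating rate (the total addiction
#' rate integrated over age).
#'
#' @param mu overdose mortality rate of the SUD population, per year (> 0).
#' @param r0 base modulating addiction rate, per year (>= 0; the filter keeps
#'   it strictly positive through the exponential transform).
#' @param alpha1,alpha2 gamma shape parameters (> 0, dimensionless).
#' @param beta1,beta2 gamma rate parameters (> 0, per year).
#' @return an object of class \code{sud_params}.
#' @export
#' @examples
#' p <- sud_params() # model defaults: gamma means alpha/beta = 45 years
#' addiction_rate(45, p)
sud_params <- function(mu = 7e-4, r0 = 0.04, alpha1 = 15, beta1 = 1 / 3,
                       alpha2 = 15, beta2 = 1 / 3) {
  vals <- c(mu = mu, r0 = r0, alpha1 = alpha1, beta1 = beta1,
            alpha2 = alpha2, beta2 = beta2)
  if (!all(is.finite(vals))) stop("sud_params: all parameters must be finite")
  if (!(mu > 0)) stop("sud_params: mu must be > 0")
  if (r0 < 0) stop("sud_params: r0 must be >= 0")
  if (!all(c(alpha1, beta1, alpha2, beta2) > 0))
    stop("sud_params: gamma shape/rate parameters must be > 0")
  structure(as.list(vals), class = "sud_params")
}

#' Linear total-population model
#'
#' \code{N(year) = N0 + delta_N * (year - ref_year)}: a linear fit to the
#' quasi-linear US population growth, anchored at calendar year 2000 and
#' extrapolated linearly outside the fitted window (e.g. back to a 1998
#' simulation start).
#'
#' @param N0 population at \code{ref_year}, persons.
#' @param delta_N population growth, persons per year.
#' @param ref_year calendar year at which \code{N = N0}.
#' @return an object of class \code{population_model}.
#' @export
population_model <- function(N0 = 274.9e6, delta_N = 2.3e6, ref_year = 2000) {
  stopifnot(N0 > 0)
  structure(list(N0 = N0, delta_N = delta_N, ref_year = ref_year),
            class = "population_model")
}

#' Population size at a calendar year (fractional years allowed)
#' @param pop a \code{\link{population_model}}.
#' @param year calendar year(s).
#' @return persons.
#' @export
population_at <- function(pop, year) {
  pop$N0 + pop$delta_N * (year - pop$ref_year)
}

#' Age-dependent addiction rate
#'
#' The gamma-mixture influx rate \code{r(a)}; integrates to \code{r0} over
#' all ages and is symmetric under swapping the two components.
#'
#' @param a age(s), years (>= 0); vectorized.
#' @param params a \code{\link{sud_params}} object.
#' @return per-year rates.
#' @export
addiction_rate <- function(a, params) {
  stopifnot(inherits(params, "sud_params"))
  (params$r0 / 2) * (stats::dgamma(a, shape = params$alpha1, rate = params$beta1) +
                     stats::dgamma(a, shape = params$alpha2, rate = params$beta2))
}

#' Closed-form age integral of the addiction rate
#'
#' \code{integral of r(s) ds} over \code{[a_lo, a_hi]} via the gamma
#' cumulative distribution functions; appears inside the survival
#' exponentials of the characteristic solution.
#'
#' @param a_lo,a_hi integration limits in years, \code{0 <= a_lo <= a_hi}
#'   (vectorized; \code{Inf} allowed).
#' @param params a \code{\link{sud_params}} object.
#' @return dimensionless integral values.
#' @export
cumulative_addiction_integral <- function(a_lo, a_hi, params) {
  stopifnot(inherits(params, "sud_params"))
  if (any(a_lo < 0) || any(a_hi < a_lo))
    stop("cumulative_addiction_integral: need 0 <= a_lo <= a_hi")
  (params$r0 / 2) *
    (stats::pgamma(a_hi, shape = params$alpha1, rate = params$beta1) -
     stats::pgamma(a_lo, shape = params$alpha1, rate = params$beta1) +
     stats::pgamma(a_hi, shape = params$alpha2, rate = params$beta2) -
     stats::pgamma(a_lo, shape = params$alpha2, rate = params$beta2))
}

# Population at model time s (years since start_year).
.pop_model_time <- function(pop, s, start_year) {
  population_at(pop, start_year + s)
}

#' Density of the SUD population (closed-form characteristic solution)
#'
#' The SUD adaptation substitutes, in the general model, mortality
#' \code{mu + r(a)} (people leave the at-risk pool by overdose death or are
#' already addicted) and influx \code{r(a) N(t)}; with a zero initial density
#' the characteristic solution reduces to a single age integral whose
#' exponent uses the closed-form \code{\link{cumulative_addiction_integral}}.
#' This evaluator computes that integral by adaptive quadrature, point by
#' point; see \code{\link{sud_density_profile}} for the vectorized grid
#' version used in simulations.
#'
#' @param a age(s), years; vectorized.
#' @param t time since the simulation start, years (scalar).
#' @param params a \code{\link{sud_params}} object.
#' @param pop a \code{\link{population_model}}.
#' @param start_year calendar year of \code{t = 0}.
#' @param rel_tol,abs_tol quadrature tolerances.
#' @return density values, persons per year of age.
#' @export
sud_density <- function(a, t, params, pop = population_model(),
                        start_year = 1998, rel_tol = 1e-10, abs_tol = 1e-10) {
  stopifnot(inherits(params, "sud_params"), inherits(pop, "population_model"),
            length(t) == 1)
  if (any(a < 0) || t < 0) stop("sud_density: need a >= 0, t >= 0")
  if (t == 0 || params$r0 == 0) return(numeric(length(a)) + 0 * a)
  mu <- params$mu
  vapply(as.numeric(a), function(ai) {
    where <- sprintf("(a = %g, t = %g)", ai, t)
    if (ai == 0) return(0)
    if (ai >= t) {
      # characteristic from (ai - t, 0); substitute u = age along it
      f <- function(u) {
        addiction_rate(u, params) *
          .pop_model_time(pop, u - ai + t, start_year) *
          exp(-mu * (ai - u) - cumulative_addiction_integral(u, ai, params))
      }
      .quad(f, ai - t, ai, rel_tol, abs_tol, where)
    } else {
      f <- function(u) {
        addiction_rate(u, params) *
          .pop_model_time(pop, u + t - ai, start_year) *
          exp(-mu * (ai - u) - cumulative_addiction_integral(u, ai, params))
      }
      .quad(f, 0, ai, rel_tol, abs_tol, where)
    }
  }, numeric(1))
}

#' Time derivative of the SUD density at fixed age
#'
#' Leibniz differentiation of the closed-form solution gives, for
#' \code{a >= t}, a boundary term (the characteristic entering from the
#' initial time carries influx at the start population) plus
#' \code{delta_N} times the survival-weighted influx integral; for
#' \code{a < t} only the latter survives. Equivalent to
#' \code{-dn/da - (mu + r(a)) n + r(a) N(t)} with the age derivative taken
#' analytically, and state-independent: the rate depends only on
#' \code{(a, t)} and the parameters.
#'
#' @inheritParams sud_density
#' @return rate values, persons per year of age per year.
#' @export
sud_rate_of_change <- function(a, t, params, pop = population_model(),
                               start_year = 1998,
                               rel_tol = 1e-10, abs_tol = 1e-10) {
  stopifnot(inherits(params, "sud_params"), length(t) == 1)
  if (any(a < 0) || t < 0) stop("sud_rate_of_change: need a >= 0, t >= 0")
  if (params$r0 == 0) return(numeric(length(a)) + 0 * a)
  mu <- params$mu
  dN <- pop$delta_N
  N_start <- .pop_model_time(pop, 0, start_year)
  vapply(as.numeric(a), function(ai) {
    where <- sprintf("(a = %g, t = %g)", ai, t)
    if (ai == 0) return(0)
    lower <- max(ai - t, 0)
    f <- function(u) {
      addiction_rate(u, params) *
        exp(-mu * (ai - u) - cumulative_addiction_integral(u, ai, params))
    }
    growth <- dN * .quad(f, lower, ai, rel_tol, abs_tol, where)
    boundary <- if (ai >= t) {
      addiction_rate(ai - t, params) * N_start *
        exp(-mu * t - cumulative_addiction_integral(ai - t, ai, params))
    } else 0
    boundary + growth
  }, numeric(1))
}

# Trapezoid cumulative integral of y over a uniform grid with spacing h;
# returns the running integral at the grid points (first value 0).
.cumtrapz <- function(y, h) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * h))
}

#' SUD density on a whole age grid (vectorized closed form)
#'
#' Fast evaluation of \code{\link{sud_density}} at every grid age at one
#' time, using running trapezoid integrals of the influx on a refined age
#' grid instead of per-point adaptive quadrature. Accuracy is set by the
#' refinement factor (age step \code{delta_a / refine}).
#'
#' @param grid an \code{\link{age_time_grid}}.
#' @param t time since simulation start, years.
#' @param params a \code{\link{sud_params}}.
#' @param pop a \code{\link{population_model}}.
#' @param start_year calendar year of \code{t = 0}.
#' @param refine integer subdivision of \code{delta_a} for the running
#'   integrals.
#' @return numeric vector of densities at \code{grid_ages(grid)}.
#' @export
sud_density_profile <- function(grid, t, params, pop = population_model(),
                                start_year = 1998, refine = 6L) {
  stopifnot(inherits(grid, "age_time_grid"))
  if (t < 0) stop("sud_density_profile: t must be >= 0")
  ages <- grid_ages(grid)
  if (t == 0 || params$r0 == 0) return(numeric(length(ages)))
  h <- grid$delta_a / refine
  fine <- seq(grid$a0, grid$a_max, by = h)
  mu <- params$mu; dN <- pop$delta_N
  B <- .pop_model_time(pop, 0, start_year) # population at model time 0
  r_f <- addiction_rate(fine, params)
  R_f <- .cumtrapz(r_f, h)                          # integral of r on [0, a]
  w <- exp(mu * fine + R_f)
  G_f <- .cumtrapz(r_f * w, h)
  G2_f <- .cumtrapz(fine * r_f * w, h)
  interp <- function(v, x) stats::approx(fine, v, xout = x, rule = 2)$y
  lower <- pmax(ages - t, 0)
  # n(a,t) = e^{-mu a - R(a)} [ (B + dN (t - a)) (G(a) - G(lo)) + dN (G2(a) - G2(lo)) ]
  damp <- exp(-mu * ages - interp(R_f, ages))
  Ga <- interp(G_f, ages); G2a <- interp(G2_f, ages)
  Glo <- interp(G_f, lower); G2lo <- interp(G2_f, lower)
  pmax(damp * ((B + dN * (t - ages)) * (Ga - Glo) + dN * (G2a - G2lo)), 0)
}

#' Advance a cumulative death field by one time step
#'
#' Rectangle-rule accumulation of overdose deaths per year of age:
#' \code{Dtil(a_j, t + delta_t) = Dtil(a_j, t) + delta_t * mu * n(a_j, t)}.
#' Negative density values (possible transiently under filter noise) are
#' clipped to zero for the death increment.
#'
#' @param D_prev a \code{\link{cumulative_death_field}}.
#' @param n_now a \code{\link{density_field}} on the same grid.
#' @param mu mortality rate, per year.
#' @param delta_t time step, years (> 0).
#' @return the advanced \code{cumulative_death_field}.
#' @export
accumulate_deaths <- function(D_prev, n_now, mu, delta_t) {
  stopifnot(inherits(D_prev, "cumulative_death_field"),
            inherits(n_now, "density_field"), delta_t > 0, mu >= 0)
  if (!identical(D_prev$grid, n_now$grid))
    stop("accumulate_deaths: fields must share one grid")
  inc <- delta_t * mu * pmax(n_now$values, 0)
  cumulative_death_field(D_prev$grid, D_prev$t + delta_t, D_prev$values + inc)
}
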