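#' Parameters of the analytically solvable toy model
#'
#' Constant per-capita mortality rate \code{mu} and influx-shape rate
#' \code{lam}: the influx of new cases is \code{p(a) = a * exp(-lam * a)}
#' (peaked at age \code{1/lam}, mean entry age \code{2/lam}), the initial
#' density is zero and nobody enters at age zero.
#'
#' @param mu mortality rate, per year (> 0).
#' @param lam influx shape rate, per year (> 0).
#' @return an object of class \code{toy_params}.
#' @export
toy_params <- function(mu, lam) {
  stopifnot(is.numeric(mu), is.numeric(lam), length(mu) == 1, length(lam) == 1)
  if (!(mu > 0) || !(lam > 0)) stop("toy_params: mu and lam must be > 0")
  structure(list(mu = mu, lam = lam), class = "toy_params")
}

# Threshold below which |lam - mu| triggers the series (degenerate-limit)
# branch of the closed forms; the raw formulas have (lam - mu)^2 denominators.
.toy_degenerate_eps <- 1e-6

#' Closed-form density of the toy age-structured model
#'
#' Evaluates the method-of-characteristics solution for constant mortality
#' \code{mu}, influx \code{p(a) = a exp(-lam a)}, zero initial density and a
#' zero age-0 boundary. Two branches meet continuously at \code{a = t}:
#' for \code{a >= t} the characteristic starts on the initial-time axis, for
#' \code{a < t} on the age-0 axis (where the solution is already stationary).
#' Near the degenerate point \code{lam = mu} a second-order series in
#' \code{(lam - mu)} replaces the raw expression to avoid cancellation.
#'
#' @param a age(s), years (>= 0); vectorized.
#' @param t time(s), years (>= 0); recycled against \code{a}.
#' @param params a \code{\link{toy_params}} object.
#' @return density values, persons per year of age (non-negative).
#' @export
#' @examples
#' p <- toy_params(mu = 0.08, lam = 0.2)
#' toy_density(30, 10, p)
toy_density <- function(a, t, params) {
  stopifnot(inherits(params, "toy_params"))
  n <- max(length(a), length(t))
  a <- rep_len(as.numeric(a), n); t <- rep_len(as.numeric(t), n)
  if (any(a < 0) || any(t < 0)) stop("toy_density: a and t must be >= 0")
  mu <- params$mu; lam <- params$lam; d <- lam - mu
  out <- numeric(n)
  up <- a >= t      # characteristic from the initial-time axis
  if (abs(d) < .toy_degenerate_eps) {
    # second-order series in d around lam = mu
    if (any(up)) {
      aa <- a[up]; tt <- t[up]
      poly <- (aa * tt - tt^2 / 2) - d * (aa * tt^2 / 2 - tt^3 / 6) +
        d^2 * (aa * tt^3 / 6 - tt^4 / 24)
      out[up] <- exp(-lam * (aa - tt) - mu * tt) * poly
    }
    if (any(!up)) {
      aa <- a[!up]
      out[!up] <- exp(-mu * aa) * (aa^2 / 2 - d * aa^3 / 3 + d^2 * aa^4 / 8)
    }
  } else {
    if (any(up)) {
      aa <- a[up]; tt <- t[up]
      out[up] <- exp(-lam * (aa - tt)) / d^2 *
        (exp(-mu * tt) * (1 + (aa - tt) * d) - (1 + aa * d) * exp(-lam * tt))
    }
    if (any(!up)) {
      aa <- a[!up]
      out[!up] <- (exp(-mu * aa) - (1 + aa * d) * exp(-lam * aa)) / d^2
    }
  }
  pmax(out, 0)
}

#' Stationary age profile of the toy model
#'
#' The long-time limit \code{n(a, t -> Inf)}, i.e. the time-independent
#' branch of the closed-form solution; equals \code{toy_density(a, t)}
#' for any \code{t > a}.
#'
#' @inheritParams toy_density
#' @return density values, persons per year of age.
#' @export
toy_steady_state <- function(a, params) {
  toy_density(a, t = max(a) + 1, params)
}

#' Closed-form time derivative of the toy density
#'
#' The rate of change of \code{n(a, t)} at fixed age, used by the ensemble
#' Kalman filter's forecast step: \code{(a - t) exp(-lam (a - t) - mu t)} for
#' \code{a >= t} and 0 for \code{a < t} (the younger-than-\code{t} branch is
#' already stationary).
#'
#' @inheritParams toy_density
#' @return rate values, persons per year of age per year.
#' @export
toy_rate_of_change <- function(a, t, params) {
  stopifnot(inherits(params, "toy_params"))
  n <- max(length(a), length(t))
  a <- rep_len(as.numeric(a), n); t <- rep_len(as.numeric(t), n)
  if (any(a < 0) || any(t < 0)) stop("toy_rate_of_change: a and t must be >= 0")
  mu <- params$mu; lam <- params$lam
  ifelse(a >= t, (a - t) * exp(-lam * (a - t) - mu * t), 0)
}

#' Age of the density maximum over time
#'
#' The toy density's maximum over age moves along
#' \code{a_max(t) = t / (1 - exp(-(lam - mu) t)) - mu / (lam (lam - mu))},
#' an increasing function with \code{a_max(t) > t}. The \code{t -> 0} limit
#' is \code{1/lam}, the age at which the influx profile peaks.
#'
#' @param t time(s), years (>= 0); vectorized.
#' @param params a \code{\link{toy_params}} object with \code{lam != mu}.
#' @return ages in years.
#' @export
peak_trajectory <- function(t, params) {
  stopifnot(inherits(params, "toy_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("peak_trajectory: t must be >= 0")
  mu <- params$mu; lam <- params$lam; d <- lam - mu
  if (abs(d) < .toy_degenerate_eps) {
    # series limit as lam -> mu
    return(1 / lam + t / 2 + d * t^2 / 12)
  }
  out <- t / (-expm1(-d * t)) - mu / (lam * d) # expm1: stable as t -> 0
  out[t == 0] <- 1 / lam
  out
}

#' Specification of a general age-structured mortality model
#'
#' Transport equation in age and time for a density \code{n(a, t)} with
#' age- and time-dependent mortality sink \code{mu(a, t)}, source
#' \code{p(a, t)}, initial density \code{rho(a)} at \code{t = t0} and a
#' fixed zero boundary at age 0 (no newborns enter the modelled population).
#'
#' @param mortality function \code{(a, t) -> per-year rate}, >= 0.
#' @param influx function \code{(a, t) -> persons/year^2}, >= 0.
#' @param initial_density function \code{(a) -> persons/year}, >= 0;
#'   defaults to zero.
#' @return an object of class \code{general_model_spec}.
#' @export
general_model_spec <- function(mortality, influx,
                               initial_density = function(a) 0 * a) {
  stopifnot(is.function(mortality), is.function(influx),
            is.function(initial_density))
  structure(list(mortality = mortality, influx = influx,
                 initial_density = initial_density),
            class = "general_model_spec")
}

#' Toy model expressed as a general model specification
#' @param params a \code{\link{toy_params}} object.
#' @return a \code{\link{general_model_spec}}.
#' @export
toy_spec <- function(params) {
  mu <- params$mu; lam <- params$lam
  general_model_spec(
    mortality = function(a, t) rep_len(mu, length(a)),
    influx = function(a, t) a * exp(-lam * a),
    initial_density = function(a) 0 * a
  )
}

# Adaptive quadrature wrapper: explicit failure with the offending point.
.quad <- function(f, lower, upper, rel_tol, abs_tol, where) {
  if (upper <= lower) return(0)
  res <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel_tol, abs.tol = abs_tol,
                     stop.on.error = TRUE),
    error = function(e) stop(sprintf(
      "quadrature failed at %s: %s", where, conditionMessage(e)), call. = FALSE)
  )
  res$value
}

#' Characteristic (formal) solution of the general model by quadrature
#'
#' Evaluates the formal method-of-characteristics solution of the general
#' age-structured model by nested adaptive quadrature. For
#' \code{a >= t - t0} the value is the decayed initial condition plus the
#' influx accumulated along the characteristic from the initial time; for
#' \code{a < t - t0} it is the influx accumulated along the characteristic
#' from the age-0 boundary (which carries zero density). Used mainly as the
#' independent oracle for the closed-form evaluators.
#'
#' @param spec a \code{\link{general_model_spec}}.
#' @param a age, years (scalar, >= 0).
#' @param t time, years (scalar, >= t0).
#' @param t0 initial time, years.
#' @param rel_tol,abs_tol quadrature tolerances.
#' @return density value, persons per year of age.
#' @export
characteristic_solution <- function(spec, a, t, t0 = 0,
                                    rel_tol = 1e-10, abs_tol = 1e-10) {
  stopifnot(inherits(spec, "general_model_spec"),
            length(a) == 1, length(t) == 1)
  if (a < 0 || t < t0) stop("characteristic_solution: need a >= 0, t >= t0")
  where <- sprintf("(a = %g, t = %g)", a, t)
  mu <- spec$mortality; p <- spec$influx
  mu_int <- function(lo, hi, age_of_s) {
    .quad(function(s) mu(age_of_s(s), s), lo, hi, rel_tol, abs_tol, where)
  }
  if (a >= t - t0) {
    # characteristic from (a - t + t0, t0)
    surv0 <- exp(-mu_int(t0, t, function(s) a - t + s))
    term1 <- spec$initial_density(a - t + t0) * surv0
    integrand <- function(s) {
      vapply(s, function(si) {
        p(si + a - t, si) * exp(-mu_int(si, t, function(u) a - t + u))
      }, numeric(1))
    }
    term1 + .quad(integrand, t0, t, rel_tol, abs_tol, where)
  } else {
    # characteristic from (0, t - a)
    integrand <- function(s) {
      vapply(s, function(si) {
        p(si, si + t - a) * exp(-mu_int(si, a, function(u) u + t - a))
      }, numeric(1))
    }
    .quad(integrand, 0, a, rel_tol, abs_tol, where)
  }
}
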