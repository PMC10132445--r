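#' Age-time discretization grid
#'
#' Shared discretization of the age interval \code{[a0, a_max]} and the
#' simulation time interval used by the model evaluators and the ensemble
#' Kalman filter. Ages are cell left edges \code{a_j = a0 + j * delta_a},
#' \code{0 <= j <= n_age - 1}; grid values are point evaluations of the
#' density at those ages (persons per year of age), not cell averages.
#'
#' @param n_age number of age cells (default 1000, giving
#'   \code{delta_a = 0.12} year on \code{[0, 120]}).
#' @param a_max upper end of the age interval in years.
#' @param delta_t time step in years.
#' @param n_steps number of forward time steps.
#' @param a0 left end of the age interval in years.
#' @param t0 initial time in years (0 throughout).
#' @return an object of class \code{age_time_grid}.
#' @export
#' @examples
#' g <- age_time_grid(n_age = 10, a_max = 120, delta_t = 0.1, n_steps = 5)
#' grid_ages(g)
age_time_grid <- function(n_age = 1000, a_max = 120, delta_t = 0.1,
                          n_steps = 100, a0 = 0, t0 = 0) {
  stopifnot(n_age >= 2, a_max > a0, delta_t > 0, n_steps >= 0)
  g <- list(
    a0 = a0, a_max = a_max, n_age = as.integer(n_age),
    delta_a = (a_max - a0) / n_age,
    t0 = t0, delta_t = delta_t, n_steps = as.integer(n_steps)
  )
  class(g) <- "age_time_grid"
  g
}

#' Ages (cell left edges) of a grid
#' @param grid an \code{age_time_grid}.
#' @return numeric vector of length \code{n_age}.
#' @export
grid_ages <- function(grid) {
  grid$a0 + (seq_len(grid$n_age) - 1L) * grid$delta_a
}

#' Time points of a grid
#' @param grid an \code{age_time_grid}.
#' @return numeric vector of length \code{n_steps + 1} starting at \code{t0}.
#' @export
grid_times <- function(grid) {
  grid$t0 + (0:grid$n_steps) * grid$delta_t
}

#' @export
print.age_time_grid <- function(x, ...) {
  cat(sprintf(
    "age_time_grid: ages [%g, %g] in %d cells (delta_a = %g yr); t0 = %g, delta_t = %g yr, %d steps\n",
    x$a0, x$a_max, x$n_age, x$delta_a, x$t0, x$delta_t, x$n_steps
  ))
  invisible(x)
}

#' Density field on an age grid at one time
#'
#' Thin container pairing a grid with the density values \code{n(a_j, t)}
#' (persons per year of age) at a single time.
#'
#' @param grid an \code{age_time_grid}.
#' @param t time in years.
#' @param values numeric vector of length \code{n_age}.
#' @return an object of class \code{density_field}.
#' @export
density_field <- function(grid, t, values) {
  stopifnot(inherits(grid, "age_time_grid"), length(values) == grid$n_age)
  structure(list(grid = grid, t = t, values = as.numeric(values)),
            class = "density_field")
}

#' Cumulative death field on an age grid at one time
#'
#' Cumulative overdose deaths per year of age since the initial time,
#' \code{Dtil(a_j, t)}; non-decreasing in time cell by cell.
#'
#' @inheritParams density_field
#' @return an object of class \code{cumulative_death_field}.
#' @export
cumulative_death_field <- function(grid, t, values) {
  stopifnot(inherits(grid, "age_time_grid"), length(values) == grid$n_age)
  if (any(values < 0)) stop("cumulative death values must be non-negative")
  structure(list(grid = grid, t = t, values = as.numeric(values)),
            class = "cumulative_death_field")
}
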