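#' Irregular age-bin schema of the mortality data
#'
#' The 22 age groups used by CDC WONDER multiple-cause-of-death exports:
#' edges 0, 1, 5, 10, 15, ..., 100, 120 years, i.e. widths
#' (1, 4, 5 x 19, 20). The model's fine age grid is coarse-grained onto
#' these bins by the measurement operator.
#'
#' @param edges 23 strictly increasing ages in years covering [0, 120].
#' @param labels optional 22 group labels; defaults to WONDER-style labels
#'   ("< 1 year", "1-4 years", ..., "100+ years").
#' @return an object of class \code{age_bin_schema}.
#' @export
#' @examples
#' s <- cdc_age_bins()
#' s$labels[1:3]
age_bin_schema <- function(edges, labels = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) != 23 || any(diff(edges) <= 0))
    stop("age_bin_schema: need 23 strictly increasing edges")
  widths <- diff(edges)
  expected <- c(1, 4, rep(5, 19), 20)
  if (!isTRUE(all.equal(widths, expected)) ||
      edges[1] != 0 || edges[23] != 120)
    stop("age_bin_schema: edges must give widths (1, 4, 5 x 19, 20) on [0, 120]")
  if (is.null(labels)) {
    labels <- c("< 1 year", "1-4 years",
                sprintf("%d-%d years", seq(5, 95, by = 5), seq(9, 99, by = 5)),
                "100+ years")
  }
  if (length(labels) != 22) stop("age_bin_schema: need 22 labels")
  structure(list(edges = edges, labels = as.character(labels)),
            class = "age_bin_schema")
}

#' Default CDC WONDER 22-group age-bin schema
#' @return an \code{\link{age_bin_schema}}.
#' @export
cdc_age_bins <- function() {
  age_bin_schema(c(0, 1, seq(5, 100, by = 5), 120))
}

#' Coarse-graining weight matrix from a model grid to age bins
#'
#' Builds the 22 x \code{n_age} matrix \code{W} such that \code{W \%*\% v}
#' integrates a per-year-of-age field given at the grid ages over each age
#' bin. The field is treated as piecewise linear between grid points
#' (trapezoid rule) with constant extrapolation on the stub between the last
#' grid age and 120; cells straddling a bin edge are apportioned linearly,
#' so the bin values sum exactly to the integral over [0, 120].
#'
#' @param grid an \code{\link{age_time_grid}}; must resolve the finest bin
#'   (\code{delta_a < 1} year).
#' @param schema an \code{\link{age_bin_schema}}.
#' @return a 22 x \code{n_age} numeric matrix.
#' @export
coarse_grain_matrix <- function(grid, schema = cdc_age_bins()) {
  stopifnot(inherits(grid, "age_time_grid"), inherits(schema, "age_bin_schema"))
  if (grid$delta_a >= 1)
    stop("coarse_grain_matrix: grid too coarse; need delta_a < 1 year so the 1-year bin contains at least one cell")
  ages <- grid_ages(grid)
  n <- grid$n_age
  W <- matrix(0, nrow = 22, ncol = n)
  edges <- schema$edges
  # piecewise-linear cells between consecutive grid ages
  add_segment <- function(j_lo, x_lo, x_hi, cell_lo, cell_hi) {
    # integrate the linear interpolant on [x_lo, x_hi] within cell
    # [cell_lo, cell_hi] spanned by grid points j_lo, j_lo + 1
    len <- x_hi - x_lo
    if (len <= 0) return(NULL)
    al <- (x_lo - cell_lo) / (cell_hi - cell_lo)
    ah <- (x_hi - cell_lo) / (cell_hi - cell_lo)
    bin <- findInterval(x_lo, edges, rightmost.closed = TRUE)
    W[bin, j_lo] <<- W[bin, j_lo] + len / 2 * ((1 - al) + (1 - ah))
    W[bin, j_lo + 1L] <<- W[bin, j_lo + 1L] + len / 2 * (al + ah)
  }
  for (j in seq_len(n - 1L)) {
    lo <- ages[j]; hi <- ages[j + 1L]
    cuts <- sort(unique(c(lo, hi, edges[edges > lo & edges < hi])))
    for (k in seq_len(length(cuts) - 1L))
      add_segment(j, cuts[k], cuts[k + 1L], lo, hi)
  }
  # constant-extrapolation stub [last grid age, 120]
  lo <- ages[n]; hi <- grid$a_max
  if (hi > lo) {
    cuts <- sort(unique(c(lo, hi, edges[edges > lo & edges < hi])))
    for (k in seq_len(length(cuts) - 1L)) {
      bin <- findInterval(cuts[k], edges, rightmost.closed = TRUE)
      W[bin, n] <- W[bin, n] + (cuts[k + 1L] - cuts[k])
    }
  }
  W
}

#' Coarse-grain a per-age field onto the data's age bins
#'
#' Integrates a cumulative-death (or any per-year-of-age) field over the 22
#' age bins; the measurement operator of the assimilation pipeline applies
#' this to the cumulative-death block of the state.
#'
#' @param x a \code{\link{cumulative_death_field}}, \code{\link{density_field}}
#'   or numeric vector of grid values.
#' @param grid the \code{\link{age_time_grid}} (taken from \code{x} if it is
#'   a field object).
#' @param schema an \code{\link{age_bin_schema}}.
#' @param W optional precomputed \code{\link{coarse_grain_matrix}}.
#' @return numeric vector of 22 per-bin integrals.
#' @export
coarse_grain <- function(x, grid = NULL, schema = cdc_age_bins(), W = NULL) {
  if (inherits(x, c("cumulative_death_field", "density_field"))) {
    grid <- x$grid
    x <- x$values
  }
  if (is.null(W)) {
    if (is.null(grid)) stop("coarse_grain: supply a grid or a weight matrix")
    W <- coarse_grain_matrix(grid, schema)
  }
  drop(W %*% x)
}
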