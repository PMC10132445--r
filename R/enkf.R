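#' Layout of the augmented state vector
#'
#' The filter state stacks three blocks: the density values on the age grid,
#' optionally the cumulative-death values (SUD pipeline), and the model
#' parameters being estimated. Parameters flagged log-transformed are stored
#' as logarithms so that the Gaussian filter updates keep them positive after
#' back-transformation.
#'
#' @param n_density number of density entries (\code{n_age}).
#' @param n_deaths number of cumulative-death entries (0 for the toy model,
#'   \code{n_age} for the SUD model).
#' @param param_names character vector of parameter labels.
#' @param log_params logical, one per parameter (recycled): stored on the log
#'   scale?
#' @return an object of class \code{state_layout}.
#' @export
state_layout <- function(n_density, n_deaths = 0L, param_names,
                         log_params = TRUE) {
  stopifnot(n_density >= 1, n_deaths >= 0, length(param_names) >= 0)
  n_par <- length(param_names)
  log_params <- rep_len(as.logical(log_params), n_par)
  dim_total <- n_density + n_deaths + n_par
  structure(list(
    n_density = as.integer(n_density), n_deaths = as.integer(n_deaths),
    param_names = as.character(param_names), log_params = log_params,
    dim = as.integer(dim_total),
    idx_density = seq_len(n_density),
    idx_deaths = if (n_deaths > 0) n_density + seq_len(n_deaths) else integer(0),
    idx_params = if (n_par > 0) n_density + n_deaths + seq_len(n_par) else integer(0)
  ), class = "state_layout")
}

#' Map natural-scale parameters to their stored (transformed) representation
#'
#' Log-flagged entries are logged; others pass through. Inverse of
#' \code{\link{untransform_params}}.
#'
#' @param v numeric parameter sub-vector on the natural scale.
#' @param layout a \code{\link{state_layout}}.
#' @return the transformed sub-vector.
#' @export
transform_params <- function(v, layout) {
  stopifnot(length(v) == length(layout$param_names))
  out <- v
  if (any(layout$log_params)) {
    if (any(v[layout$log_params] <= 0))
      stop("transform_params: log-transformed parameters must be > 0")
    out[layout$log_params] <- log(v[layout$log_params])
  }
  out
}

#' Map stored parameters back to the natural scale
#' @param v numeric parameter sub-vector as stored in the state.
#' @param layout a \code{\link{state_layout}}.
#' @return the natural-scale sub-vector (log-flagged entries exponentiated).
#' @export
untransform_params <- function(v, layout) {
  stopifnot(length(v) == length(layout$param_names))
  out <- v
  out[layout$log_params] <- exp(v[layout$log_params])
  out
}

#' Draw an initial ensemble
#'
#' \code{M} independent Gaussian draws around the initial state estimate:
#' \code{chi0_i ~ N(x0, P0)}.
#'
#' @param x0 initial state estimate (length = state dimension).
#' @param P0 initial covariance: either a variance vector (diagonal) or a
#'   full symmetric positive-semidefinite matrix.
#' @param M ensemble size (>= 2).
#' @param layout a \code{\link{state_layout}}.
#' @param seed optional integer; if supplied the R RNG is seeded.
#' @return an object of class \code{ensemble}: list with the state matrix
#'   \code{X} (dim x M) and the layout.
#' @export
init_ensemble <- function(x0, P0, M, layout, seed = NULL) {
  stopifnot(M >= 2, length(x0) == layout$dim)
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- length(x0)
  if (is.matrix(P0)) {
    if (!isTRUE(all.equal(P0, t(P0), tolerance = 1e-10)))
      stop("init_ensemble: P0 must be symmetric")
    ev <- eigen(P0, symmetric = TRUE)
    if (min(ev$values) < -1e-10 * max(abs(ev$values), 1))
      stop(sprintf("init_ensemble: P0 not positive semidefinite (eigenvalue %g)",
                   min(ev$values)))
    L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    X <- x0 + L %*% matrix(stats::rnorm(d * M), d, M)
  } else {
    if (length(P0) != d) stop("init_ensemble: diagonal P0 must match state dim")
    if (any(P0 < 0)) {
      j <- which.min(P0)
      stop(sprintf("init_ensemble: P0 not positive semidefinite (variance %g at entry %d)",
                   P0[j], j))
    }
    X <- x0 + sqrt(P0) * matrix(stats::rnorm(d * M), d, M)
  }
  structure(list(X = X, layout = layout, M = as.integer(M)),
            class = "ensemble")
}

.ens_matrix <- function(e) if (inherits(e, "ensemble")) e$X else e

#' Ensemble sample mean and covariance
#'
#' Sample mean over members and the unbiased (\code{M - 1} denominator)
#' sample covariance.
#'
#' @param e an \code{\link{ensemble}} or a dim x M state matrix.
#' @param full logical: return the full covariance matrix (default) or only
#'   its diagonal (memory-friendly for large states).
#' @return list with \code{mean} and \code{cov} (or \code{var} if
#'   \code{full = FALSE}).
#' @export
ensemble_stats <- function(e, full = TRUE) {
  X <- .ens_matrix(e)
  M <- ncol(X)
  stopifnot(M >= 2)
  m <- rowMeans(X)
  A <- X - m
  if (full) list(mean = m, cov = tcrossprod(A) / (M - 1))
  else list(mean = m, var = rowSums(A * A) / (M - 1))
}

#' Forecast step of the ensemble Kalman filter
#'
#' One explicit-Euler step per member,
#' \code{chi_{k+1}^- = chi_k + delta_t f(chi_k, t_k) + eps_k}, with a
#' process-noise draw \code{eps_k ~ N(0, Q)}. Parameter blocks have zero
#' drift (\code{rate_fn} must return 0 there); they are perturbed by the
#' noise only.
#'
#' @param e an \code{\link{ensemble}}.
#' @param rate_fn function \code{(X, t) -> derivative matrix} (vectorized
#'   over members; each column uses that member's own untransformed
#'   parameters).
#' @param t_k current time, years.
#' @param delta_t step, years.
#' @param noise process-noise specification from \code{\link{process_noise}}.
#' @return the forecast ensemble.
#' @export
enkf_forecast <- function(e, rate_fn, t_k, delta_t, noise = process_noise("none")) {
  stopifnot(inherits(e, "ensemble"))
  F <- rate_fn(e$X, t_k)
  if (!all(is.finite(F))) {
    bad <- which(!is.finite(F), arr.ind = TRUE)[1, ]
    stop(sprintf("enkf_forecast: non-finite derivative at state entry %d of member %d (t = %g)",
                 bad[1], bad[2], t_k))
  }
  X <- e$X + delta_t * F
  X <- X + draw_process_noise(noise, nrow(X), ncol(X))
  e$X <- X
  e
}

#' Process-noise specification
#'
#' \code{type = "ones"} is the rank-one covariance \code{sd^2 * J} (J the
#' all-ones matrix): one scalar draw per member added to every state entry,
#' i.e. fully correlated noise. \code{type = "diag"} is independent noise
#' with the given per-entry standard deviation(s); \code{type = "none"}
#' disables process noise.
#'
#' @param type one of \code{"ones"}, \code{"diag"}, \code{"none"}.
#' @param sd scalar (\code{"ones"}) or per-entry (\code{"diag"}) standard
#'   deviation.
#' @return an object of class \code{process_noise}.
#' @export
process_noise <- function(type = c("ones", "diag", "none"), sd = 0) {
  type <- match.arg(type)
  stopifnot(all(sd >= 0))
  structure(list(type = type, sd = sd), class = "process_noise")
}

draw_process_noise <- function(noise, d, M) {
  switch(noise$type,
    none = 0,
    ones = {
      xi <- stats::rnorm(M, sd = noise$sd)
      matrix(xi, d, M, byrow = TRUE)
    },
    diag = rep_len(noise$sd, d) * matrix(stats::rnorm(d * M), d, M)
  )
}

#' Predicted observation statistics
#'
#' Maps each member through the measurement function and forms the predicted
#' observation mean, the innovation covariance
#' \code{P_zz = cov(h(chi)) + R} and the state-observation cross covariance
#' \code{P_xz}, both with the \code{M - 1} denominator.
#'
#' @param e an \code{\link{ensemble}}.
#' @param h measurement function \code{(X) -> obs x M matrix}.
#' @param R observation covariance: variance vector (diagonal) or full
#'   matrix.
#' @return list with \code{zhat}, \code{P_zz}, \code{P_xz}, and the member
#'   observations \code{Z}.
#' @export
predict_observations <- function(e, h, R) {
  X <- .ens_matrix(e)
  M <- ncol(X)
  Z <- h(X)
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = M)
  n_obs <- nrow(Z)
  Rm <- if (is.matrix(R)) R else diag(rep_len(R, n_obs), n_obs)
  if (nrow(Rm) != n_obs)
    stop(sprintf("predict_observations: h returns %d-dim observations but R is %d x %d",
                 n_obs, nrow(Rm), ncol(Rm)))
  zhat <- rowMeans(Z)
  Az <- Z - zhat
  Ax <- X - rowMeans(X)
  list(
    zhat = zhat,
    P_zz = tcrossprod(Az) / (M - 1) + Rm,
    P_xz = tcrossprod(Ax, Az) / (M - 1),
    Z = Z
  )
}

#' Kalman gain
#'
#' \code{K = P_xz P_zz^-1}, computed by solving the linear system rather
#' than forming the inverse.
#'
#' @param P_xz state-observation cross covariance (state dim x obs dim).
#' @param P_zz innovation covariance (obs dim x obs dim, invertible; a
#'   positive-definite observation noise R guarantees this).
#' @return the gain matrix (state dim x obs dim).
#' @export
kalman_gain <- function(P_xz, P_zz) {
  P_xz <- as.matrix(P_xz); P_zz <- as.matrix(P_zz)
  tryCatch(t(solve(P_zz, t(P_xz))),
           error = function(e2) stop(
             "kalman_gain: innovation covariance is singular; use a positive-definite observation noise R",
             call. = FALSE))
}

#' Perturbed-observation update step
#'
#' Each member is corrected with an independently perturbed copy of the
#' observation: \code{chi_i <- chi_i + K (z + eta_i - h(chi_i))},
#' \code{eta_i ~ N(0, R)}. The posterior covariance reported in the
#' diagnostics is the prior covariance minus \code{K P_zz K^T}.
#'
#' @param e an \code{\link{ensemble}} (the forecast/prior ensemble).
#' @param z observation vector.
#' @param h measurement function \code{(X) -> obs x M matrix}.
#' @param R observation covariance (variance vector or matrix).
#' @param obs optional precomputed result of \code{\link{predict_observations}}.
#' @return list with the updated \code{ensemble}, the gain \code{K}, the
#'   prediction statistics, and \code{post_var}: the diagonal of the
#'   posterior covariance \code{P^- - K P_zz K^T}.
#' @export
enkf_update <- function(e, z, h, R, obs = NULL) {
  stopifnot(inherits(e, "ensemble"))
  if (is.null(obs)) obs <- predict_observations(e, h, R)
  n_obs <- length(obs$zhat)
  if (length(z) != n_obs)
    stop(sprintf("enkf_update: observation has length %d but h returns %d values",
                 length(z), n_obs))
  M <- e$M
  K <- kalman_gain(obs$P_xz, obs$P_zz)
  eta <- if (is.matrix(R)) {
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    L %*% matrix(stats::rnorm(n_obs * M), n_obs, M)
  } else {
    sqrt(rep_len(R, n_obs)) * matrix(stats::rnorm(n_obs * M), n_obs, M)
  }
  prior_var <- ensemble_stats(e$X, full = FALSE)$var
  innov <- (z + eta) - obs$Z
  e$X <- e$X + K %*% innov
  # diag(K P_zz K^T) = diag(P_xz K^T) since K = P_xz P_zz^-1 and P_zz symmetric
  post_var <- prior_var - rowSums(obs$P_xz * K)
  list(ensemble = e, K = K, obs = obs, post_var = post_var,
       gain_norm = sqrt(sum(K^2)))
}

#' Run the augmented ensemble Kalman filter
#'
#' Alternates explicit-Euler forecast steps with perturbed-observation
#' updates on the observation schedule, recording parameter trajectories
#' (ensemble means of the natural-scale parameters and their spreads) and
#' update diagnostics. After the last observation the loop continues in pure
#' forecast mode, so the same routine produces out-of-sample forecasts.
#'
#' @param ens initial \code{\link{ensemble}} (from \code{\link{init_ensemble}}).
#' @param rate_fn state derivative function \code{(X, t) -> matrix}.
#' @param h measurement function \code{(X) -> obs x M matrix}.
#' @param obs_times times of the observations (must lie on the step grid).
#' @param obs_z observation matrix, obs dim x length(obs_times).
#' @param t0 initial time, years.
#' @param delta_t step, years.
#' @param n_steps number of forecast steps.
#' @param Q a \code{\link{process_noise}} specification.
#' @param R observation covariance (variance vector or matrix).
#' @param record_predictions logical: store the predicted observation mean
#'   and spread immediately before each update (and at every step after the
#'   last observation when \code{forecast_record = TRUE}).
#' @param forecast_record logical: also record \code{h} statistics at every
#'   pure-forecast step beyond the last observation.
#' @return an object of class \code{enkf_fit}: list with the final ensemble,
#'   per-step times, natural-scale parameter mean/sd trajectories
#'   (\code{param_mean}, \code{param_sd}; steps x parameters), per-update
#'   diagnostics (\code{update_times}, \code{gain_norm}, \code{post_var}),
#'   and recorded predictions (\code{pred_times}, \code{pred_mean},
#'   \code{pred_sd}).
#' @export
run_enkf <- function(ens, rate_fn, h, obs_times, obs_z,
                     t0 = 0, delta_t = 0.1, n_steps = 100,
                     Q = process_noise("ones", 1e-2), R = 1e-4,
                     record_predictions = TRUE, forecast_record = FALSE) {
  stopifnot(inherits(ens, "ensemble"))
  layout <- ens$layout
  times <- t0 + (0:n_steps) * delta_t
  obs_idx <- integer(0)
  if (length(obs_times)) {
    obs_idx <- vapply(obs_times, function(tt) {
      j <- which(abs(times - tt) < 1e-9)
      if (length(j) != 1)
        stop(sprintf("run_enkf: observation time %g is not on the step grid", tt))
      j
    }, integer(1))
    if (is.null(dim(obs_z))) obs_z <- matrix(obs_z, ncol = length(obs_times))
    stopifnot(ncol(obs_z) == length(obs_times))
  }
  n_par <- length(layout$idx_params)
  param_mean <- matrix(NA_real_, n_steps + 1, n_par,
                       dimnames = list(NULL, layout$param_names))
  param_sd <- param_mean
  rec_param <- function(k) {
    if (n_par == 0) return(invisible())
    P <- ens$X[layout$idx_params, , drop = FALSE]
    P[layout$log_params, ] <- exp(P[layout$log_params, , drop = FALSE])
    param_mean[k, ] <<- rowMeans(P)
    param_sd[k, ] <<- sqrt(rowSums((P - rowMeans(P))^2) / (ens$M - 1))
  }
  rec_param(1L)
  update_times <- c(); gain_norms <- c(); post_var_list <- list()
  pred_times <- c(); pred_mean <- list(); pred_sd <- list()
  last_obs_step <- if (length(obs_idx)) max(obs_idx) else 0L
  for (k in seq_len(n_steps)) {
    ens <- enkf_forecast(ens, rate_fn, times[k], delta_t, Q)
    j <- which(obs_idx == k + 1L)
    want_pred <- (record_predictions && length(j) == 1) ||
      (forecast_record && (k + 1L) > last_obs_step)
    obs_stats <- NULL
    if (want_pred) {
      obs_stats <- predict_observations(ens, h, R)
      pred_times <- c(pred_times, times[k + 1L])
      pred_mean[[length(pred_mean) + 1L]] <- obs_stats$zhat
      pred_sd[[length(pred_sd) + 1L]] <-
        sqrt(pmax(diag(obs_stats$P_zz), 0))
    }
    if (length(j) == 1) {
      up <- enkf_update(ens, obs_z[, j], h, R, obs = obs_stats)
      ens <- up$ensemble
      update_times <- c(update_times, times[k + 1L])
      gain_norms <- c(gain_norms, up$gain_norm)
      post_var_list[[length(post_var_list) + 1L]] <- up$post_var
    }
    rec_param(k + 1L)
  }
  structure(list(
    ensemble = ens, times = times,
    param_mean = param_mean, param_sd = param_sd,
    update_times = update_times, gain_norm = gain_norms,
    post_var = post_var_list,
    pred_times = pred_times,
    pred_mean = if (length(pred_mean)) do.call(cbind, pred_mean) else NULL,
    pred_sd = if (length(pred_sd)) do.call(cbind, pred_sd) else NULL
  ), class = "enkf_fit")
}

#' @export
print.enkf_fit <- function(x, ...) {
  cat(sprintf("enkf_fit: %d members, %d steps (t in [%g, %g]), %d updates\n",
              x$ensemble$M, length(x$times) - 1, min(x$times), max(x$times),
              length(x$update_times)))
  if (ncol(x$param_mean)) {
    est <- x$param_mean[nrow(x$param_mean), ]
    cat("final parameter means:\n")
    print(signif(est, 4))
  }
  invisible(x)
}
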