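#' Extend a 3D trajectory with velocity and acceleration columns
#'
#' Builds the 9-dimensional kinematic state used by the Kalman-filter decoder:
#' positions, velocities and accelerations, the derivatives estimated by
#' causal first differences divided by the step, with the first row replicated
#' so the output keeps N rows.
#'
#' @param y N x 3 trajectory (matrix or data frame with `time` column).
#' @param dt Sampling step in seconds.
#' @return N x 9 matrix, columns ordered (positions, velocities,
#'   accelerations).
#' @export
extend_with_derivatives <- function(y, dt) {
  ym <- traj_matrix(y)
  n <- nrow(ym)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  stopifnot(ncol(ym) == 3L, dt > 0)
  vel <- rbind(ym[2L, ] - ym[1L, ], diff(ym)) / dt
  acc <- rbind(vel[2L, ] - vel[1L, ], diff(vel)) / dt
  cbind(ym, vel, acc)
}

#' Least-squares system identification for the Kalman-filter decoder
#'
#' Estimates the linear-Gaussian state-space model
#' \eqn{y_{k+1} = A y_k + w_k}, \eqn{x_k = H y_k + q_k} from training pairs by
#' least squares on the centered data:
#' \eqn{A = Y_2 Y_1^\top (Y_1 Y_1^\top)^{-1}},
#' \eqn{H = X Y^\top (Y Y^\top)^{-1}},
#' \eqn{W = (Y_2 - A Y_1)(Y_2 - A Y_1)^\top/(N-1)},
#' \eqn{Q = (X - H Y)(X - H Y)^\top/N}, with \eqn{Y_1, Y_2} the lag-0/lag-1
#' blocks. The filter is initialized at the centered origin with covariance
#' `W`.
#'
#' @param x N x n feature matrix (observations of the filter).
#' @param y N x m state matrix (typically the derivative-extended
#'   trajectory, m = 9).
#' @param ridge Optional non-negative jitter \eqn{\delta}; \eqn{\delta I} is
#'   added to the moment matrices before inversion (default 0). Useful when
#'   the feature dimension makes the moment matrices ill-conditioned.
#' @return An object of class `kalman_params` with elements `A`, `H`, `W`,
#'   `Q`, `x_mean`, `y_mean`, `y0`, `P0`.
#' @export
kf_fit <- function(x, y, ridge = 0) {
  xm <- as.matrix(x); ym <- traj_matrix(y)
  n_obs <- nrow(xm)
  stopifnot(nrow(ym) == n_obs, ridge >= 0)
  n <- ncol(xm); m <- ncol(ym)
  if (n_obs <= max(n, m) + 1L) {
    stop("need more observations than max(feature, state) dimension + 1",
         call. = FALSE)
  }
  x_mean <- colMeans(xm); y_mean <- colMeans(ym)
  xc <- t(sweep(xm, 2L, x_mean))   # n x N, columns are observations
  yc <- t(sweep(ym, 2L, y_mean))   # m x N
  # lagged blocks centered by their own means: least squares with an
  # intercept, so an exact noiseless propagation y_{k+1} = A y_k is recovered
  # exactly even when the sample mean is nonzero
  y1 <- ym[-n_obs, , drop = FALSE]
  y2 <- ym[-1L, , drop = FALSE]
  y1 <- t(sweep(y1, 2L, colMeans(y1)))
  y2 <- t(sweep(y2, 2L, colMeans(y2)))
  inv_or_stop <- function(mm, what) {
    mm <- mm + ridge * diag(nrow(mm))
    tryCatch(solve(mm), error = function(e) {
      stop(sprintf("singular moment matrix in %s; consider a small ridge jitter (kf_fit(..., ridge = delta))", what),
           call. = FALSE)
    })
  }
  a <- y2 %*% t(y1) %*% inv_or_stop(y1 %*% t(y1), "state transition")
  h <- xc %*% t(yc) %*% inv_or_stop(yc %*% t(yc), "observation map")
  wres <- y2 - a %*% y1
  w <- wres %*% t(wres) / (n_obs - 1L)
  qres <- xc - h %*% yc
  q <- qres %*% t(qres) / n_obs
  structure(
    list(A = a, H = h, W = (w + t(w)) / 2, Q = (q + t(q)) / 2,
         x_mean = x_mean, y_mean = y_mean,
         y0 = rep(0, m), P0 = (w + t(w)) / 2),
    class = "kalman_params"
  )
}

#' Run the Kalman-filter recursion over a feature stream
#'
#' Standard predict/update recursion with time-invariant parameters:
#' \eqn{\hat y^-_k = A\hat y_{k-1}}, \eqn{P^-_k = A P_{k-1} A^\top + W},
#' gain \eqn{K_k = P^-_k H^\top (H P^-_k H^\top + Q)^{-1}},
#' \eqn{\hat y_k = \hat y^-_k + K_k (x_k - H \hat y^-_k)},
#' \eqn{P_k = (I - K_k H) P^-_k} (symmetrized each step). Features are
#' centered internally with the stored training mean and predictions are
#' returned on the original state scale.
#'
#' @param params A fitted `kalman_params`.
#' @param x_stream N x n feature matrix.
#' @param steady_state If `TRUE`, iterate the Riccati recursion to a fixed
#'   point first and use the converged gain for every step (large-n speedup;
#'   default `FALSE`, the literal per-step recursion).
#' @param ridge Optional jitter added to the innovation covariance before
#'   inversion (default 0).
#' @return N x m matrix of filtered state estimates.
#' @export
kf_filter <- function(params, x_stream, steady_state = FALSE, ridge = 0) {
  stopifnot(inherits(params, "kalman_params"))
  xm <- as.matrix(x_stream)
  n_steps <- nrow(xm)
  xc <- sweep(xm, 2L, params$x_mean)
  a <- params$A; h <- params$H; w <- params$W; q <- params$Q
  m <- ncol(a); n <- ncol(xm)
  stopifnot(nrow(h) == n)
  inv_innov <- function(s) {
    s <- s + ridge * diag(nrow(s))
    tryCatch(solve(s), error = function(e) {
      stop("singular innovation covariance; consider kf_filter(..., ridge = delta)",
           call. = FALSE)
    })
  }
  gain <- function(p_prior) {
    s <- h %*% p_prior %*% t(h) + q
    p_prior %*% t(h) %*% inv_innov(s)
  }
  out <- matrix(0, n_steps, m)
  y_hat <- params$y0
  p <- params$P0
  k_fix <- NULL
  if (steady_state) {
    for (it in seq_len(1000L)) {
      p_prior <- a %*% p %*% t(a) + w
      k_new <- gain(p_prior)
      p_new <- (diag(m) - k_new %*% h) %*% p_prior
      p_new <- (p_new + t(p_new)) / 2
      done <- !is.null(k_fix) && max(abs(k_new - k_fix)) < 1e-10
      k_fix <- k_new
      p <- p_new
      if (done) break
    }
  }
  for (k in seq_len(n_steps)) {
    y_prior <- a %*% y_hat
    if (steady_state) {
      kk <- k_fix
    } else {
      p_prior <- a %*% p %*% t(a) + w
      kk <- gain(p_prior)
      p <- (diag(m) - kk %*% h) %*% p_prior
      p <- (p + t(p)) / 2
    }
    y_hat <- y_prior + kk %*% (xc[k, ] - h %*% y_prior)
    out[k, ] <- y_hat
  }
  sweep(out, 2L, params$y_mean, `+`)
}

#' @export
print.kalman_params <- function(x, ...) {
  cat(sprintf("<kalman_params> state dim %d, observation dim %d\n",
              ncol(x$A), nrow(x$H)))
  invisible(x)
}

#' @method glance kalman_params
#' @export
glance.kalman_params <- function(x, ...) {
  tibble::tibble(
    state_dim = ncol(x$A),
    obs_dim = nrow(x$H),
    process_noise_tr = sum(diag(x$W)),
    obs_noise_tr = sum(diag(x$Q))
  )
}
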