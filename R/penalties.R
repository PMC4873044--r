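#' Penalty configuration for smoothness-penalized NPLS
#'
#' @param lambda Non-negative penalty weight \eqn{\lambda}.
#' @param variant `"sobolev"` (derivative penalty, SNPLS) or `"polynomial"`
#'   (Savitzky-Golay residual penalty, PNPLS).
#' @param s Derivative order for the Sobolev variant (default 3).
#' @param p Polynomial degree for the polynomial variant (default 2).
#' @param l Half-window for the polynomial variant (default 4, i.e. window
#'   length L = 2l + 1 = 9); requires `2l + 1 > p + 1` so each window fit is
#'   overdetermined.
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(lambda, variant = c("sobolev", "polynomial"),
                           s = 3L, p = 2L, l = 4L) {
  variant <- match.arg(variant)
  stopifnot(lambda >= 0, s >= 1, p >= 0, l >= 1, 2 * l + 1 > p + 1)
  structure(list(lambda = lambda, variant = variant,
                 s = as.integer(s), p = as.integer(p), l = as.integer(l)),
            class = "penalty_config")
}

#' Iterated backward differences along the observation axis
#'
#' The s-fold first difference of each feature stream (column), the discrete
#' stand-in for the s-th derivative in the Sobolev penalty. No \eqn{\Delta t}
#' scaling is applied; it is absorbed into \eqn{\lambda}. Row `i` of the
#' output corresponds to epoch `i + s`.
#'
#' @param x Numeric matrix N x features (or a vector).
#' @param s Difference order, `1 <= s < N`.
#' @return Matrix (N - s) x features.
#' @export
finite_difference <- function(x, s) {
  x <- as.matrix(x)
  stopifnot(s >= 1)
  if (nrow(x) <= s) {
    stop(sprintf("need more than s = %d rows, got %d", s, nrow(x)),
         call. = FALSE)
  }
  diff(x, differences = as.integer(s))
}

# Steady-state Savitzky-Golay smoothing weights: center row of the
# signal::sgolay projection matrix for degree p, window 2l+1.
sg_weights <- function(p, l) {
  n <- 2L * l + 1L
  fm <- signal::sgolay(p = p, n = n)
  as.numeric(unclass(fm)[l + 1L, ])
}

#' Sliding-window polynomial (Savitzky-Golay) smoothing
#'
#' For every interior row `i` (from `l + 1` to `N - l`) and every feature
#' independently, fits a degree-`p` polynomial by least squares to the window
#' `i - l .. i + l` and evaluates it at the center. This is a fixed linear
#' filter; the implementation applies the Savitzky-Golay weights from
#' [signal::sgolay()].
#'
#' @param x Numeric matrix N x features (or a vector), `N >= 2l + 1`.
#' @param p Polynomial degree.
#' @param l Half-window.
#' @return Matrix (N - 2l) x features of smoothed center values, row `j`
#'   corresponding to input row `j + l`.
#' @export
polynomial_smooth <- function(x, p = 2L, l = 4L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L * l + 1L) {
    stop(sprintf("need at least 2l + 1 = %d rows, got %d", 2L * l + 1L, n),
         call. = FALSE)
  }
  w <- sg_weights(p, l)
  out <- matrix(0, n - 2L * l, ncol(x))
  for (j in seq_along(w)) {
    off <- j - 1L
    out <- out + w[j] * x[(1L + off):(n - 2L * l + off), , drop = FALSE]
  }
  out
}

#' Augment a centered tensor/response pair with a derivative penalty block
#'
#' Builds the stacked pair of the Sobolev-penalized regression: the
#' augmented tensor stacks the centered data block over
#' \eqn{\lambda \cdot \Delta^s X} (s-fold backward differences along
#' observations, applied per feature cell), and the augmented response stacks
#' the centered responses over a zero block. Fitting NPLS to the augmented
#' pair without re-centering is the SNPLS estimator.
#'
#' @param xc Centered `epoch_tensor` or 4-way array.
#' @param yc Centered response matrix N x m.
#' @param lambda Penalty weight.
#' @param s Derivative order.
#' @return List with `x` (4-way array, (2N - s) x modes) and `y`
#'   ((2N - s) x m matrix).
#' @export
augment_sobolev <- function(xc, yc, lambda, s = 3L) {
  xv <- tensor_values(xc)
  yc <- as.matrix(yc)
  d <- dim(xv)
  stopifnot(nrow(yc) == d[1L])
  xm <- unfold_obs(xv)
  dm <- finite_difference(xm, s)
  xa <- rbind(xm, lambda * dm)
  ya <- rbind(yc, matrix(0, nrow(dm), ncol(yc)))
  list(x = fold_obs(xa, d[2:4]), y = ya)
}

#' Augment a centered tensor/response pair with a roughness-residual block
#'
#' The polynomial (PNPLS) counterpart of [augment_sobolev()]: the penalty
#' block is \eqn{\lambda (X - \widehat X)} on the interior rows, where
#' \eqn{\widehat X} is the sliding-window Savitzky-Golay smoothing of each
#' feature stream. Feature streams that are exactly degree-`p` polynomials of
#' the epoch index produce a zero block, so the penalized fit coincides with
#' plain NPLS for any \eqn{\lambda}.
#'
#' @param xc Centered `epoch_tensor` or 4-way array.
#' @param yc Centered response matrix N x m.
#' @param lambda Penalty weight.
#' @param p Polynomial degree.
#' @param l Half-window.
#' @return List with `x` ((2N - 2l) x modes array) and `y` ((2N - 2l) x m).
#' @export
augment_polynomial <- function(xc, yc, lambda, p = 2L, l = 4L) {
  xv <- tensor_values(xc)
  yc <- as.matrix(yc)
  d <- dim(xv)
  stopifnot(nrow(yc) == d[1L])
  xm <- unfold_obs(xv)
  sm <- polynomial_smooth(xm, p = p, l = l)
  resid <- xm[(l + 1L):(d[1L] - l), , drop = FALSE] - sm
  xa <- rbind(xm, lambda * resid)
  ya <- rbind(yc, matrix(0, nrow(resid), ncol(yc)))
  list(x = fold_obs(xa, d[2:4]), y = ya)
}

#' Fit a smoothness-penalized NPLS model (SNPLS / PNPLS)
#'
#' Centers the tensor and response by their training means, builds the
#' augmented pair for the configured penalty, and runs the plain NPLS core on
#' it without re-centering (so the zero response block is preserved exactly
#' and \eqn{\lambda = 0} reduces to plain NPLS). The returned model carries
#' the training means, so prediction and coefficient materialization work
#' unchanged.
#'
#' @param x An `epoch_tensor` or 4-way array.
#' @param y Response (data frame with `time` column, or matrix).
#' @param n_factors Number of latent factors.
#' @param penalty A [penalty_config()].
#' @param ... Passed to [npls_fit()] (tolerances).
#' @return An `npls_model` with an extra `penalty` element.
#' @export
penalized_npls_fit <- function(x, y, n_factors, penalty, ...) {
  stopifnot(inherits(penalty, "penalty_config"))
  xv <- tensor_values(x)
  ym <- traj_matrix(y)
  xm <- unfold_obs(xv)
  xmean <- colMeans(xm)
  ymean <- colMeans(ym)
  xc <- fold_obs(sweep(xm, 2L, xmean), dim(xv)[2:4])
  yc <- sweep(ym, 2L, ymean)
  aug <- if (penalty$variant == "sobolev") {
    augment_sobolev(xc, yc, penalty$lambda, s = penalty$s)
  } else {
    augment_polynomial(xc, yc, penalty$lambda, p = penalty$p, l = penalty$l)
  }
  model <- npls_fit(aug$x, aug$y, n_factors, center = FALSE, ...)
  model$x_mean <- xmean
  model$y_mean <- ymean
  model$penalty <- penalty
  model
}
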