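#' Prediction-quality criteria for decoded trajectories
#'
#' Four criteria compare an observed coordinate stream `y` with its prediction
#' `y_hat`:
#' * `pearson()` — sample Pearson correlation r.
#' * `rmse_norm()` — normalized L2 error
#'   \eqn{\|y-\hat y\|_2 / \|y-\bar y\|_2} (the normalizer is the centered
#'   observation norm, so predicting the mean scores exactly 1).
#' * `mae_norm()` — normalized L1 error
#'   \eqn{\|y-\hat y\|_1 / \|y-\bar y\|_1}.
#' * `made()` — mean absolute differential error: the normalized L1 error of
#'   the first-difference sequences,
#'   \eqn{\|y'-\hat y'\|_1 / \|y'-\bar{y'}\|_1}; it measures accuracy and
#'   smoothness jointly and ignores constant offsets.
#'
#' @param y,y_hat Numeric vectors of equal length.
#' @return A single number.
#' @name criteria
NULL

#' @rdname criteria
#' @export
pearson <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  stats::cor(y, y_hat)
}

#' @rdname criteria
#' @export
rmse_norm <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  denom <- sqrt(sum((y - mean(y))^2))
  if (denom == 0) stop("normalizer undefined for constant y", call. = FALSE)
  sqrt(sum((y - y_hat)^2)) / denom
}

#' @rdname criteria
#' @export
mae_norm <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  denom <- sum(abs(y - mean(y)))
  if (denom == 0) stop("normalizer undefined for constant y", call. = FALSE)
  sum(abs(y - y_hat)) / denom
}

#' @rdname criteria
#' @export
made <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 3L)
  mae_norm(diff(y), diff(y_hat))
}

#' Per-coordinate and averaged criteria for a multi-coordinate prediction
#'
#' Computes the four criteria of [criteria] for every coordinate column and
#' appends an equal-weight `"mean"` row.
#'
#' @param y,y_hat Observed and predicted trajectories: N x m matrices or data
#'   frames (a `time` column is ignored).
#' @return A tibble with columns `coordinate, r, rmse, mae, made`; the last
#'   row has `coordinate == "mean"`.
#' @export
metrics_report <- function(y, y_hat) {
  ym <- traj_matrix(y); pm <- traj_matrix(y_hat)
  stopifnot(all(dim(ym) == dim(pm)))
  cn <- colnames(ym)
  if (is.null(cn)) cn <- paste0("y", seq_len(ncol(ym)))
  rows <- lapply(seq_len(ncol(ym)), function(j) {
    tibble::tibble(
      coordinate = cn[j],
      r = pearson(ym[, j], pm[, j]),
      rmse = rmse_norm(ym[, j], pm[, j]),
      mae = mae_norm(ym[, j], pm[, j]),
      made = made(ym[, j], pm[, j])
    )
  })
  per <- dplyr::bind_rows(rows)
  dplyr::bind_rows(per, tibble::tibble(
    coordinate = "mean", r = mean(per$r), rmse = mean(per$rmse),
    mae = mean(per$mae), made = mean(per$made)
  ))
}

#' Estimate the prediction delay of a decoded stream
#'
#' Shifts the prediction forward in time over a grid of multiples of the
#' prediction step and reports the smallest shift maximizing the Pearson
#' correlation with the observed stream: shift `k` pairs `y[1..N-k]` with
#' `y_hat[(1+k)..N]`, so a prediction that lags the observation by `k` steps
#' is detected as a delay of `k * dt` seconds. Ties are broken toward the
#' smaller shift.
#'
#' @param y,y_hat Numeric vectors of equal length N.
#' @param dt Prediction step in seconds.
#' @param s_max Upper end of the searched interval `[0, s_max]` seconds
#'   (default 2).
#' @return A list of class `delay_estimate` with `delay` (seconds),
#'   `correlation` at that delay, and the searched `interval`.
#' @export
estimate_delay <- function(y, y_hat, dt, s_max = 2) {
  stopifnot(length(y) == length(y_hat), dt > 0, s_max >= 0)
  n <- length(y)
  k_max <- floor(s_max / dt + 1e-9)
  if (n - k_max < 2L) {
    stop("overlap shorter than 2 samples at the maximal shift", call. = FALSE)
  }
  cors <- vapply(0:k_max, function(k) {
    pearson(y[seq_len(n - k)], y_hat[(1L + k):n])
  }, numeric(1))
  # smallest shift attaining the maximum; exact ties (e.g. periodic signals)
  # are resolved with a small numerical tolerance
  best <- which(cors >= max(cors) - 1e-12)[1L]
  structure(
    list(delay = (best - 1L) * dt, correlation = cors[best],
         interval = c(0, s_max), correlations = cors, dt = dt),
    class = "delay_estimate"
  )
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("<delay_estimate> %.3f s (r = %.3f) over [%g, %g] s\n",
              x$delay, x$correlation, x$interval[1], x$interval[2]))
  invisible(x)
}

#' Modality influence profile of a linear decoding model
#'
#' For each modality of the coefficient array (frequency, temporal lag,
#' spatial/channel), the influence of element `i` is the sum of absolute
#' coefficient values over all other indices (including response columns),
#' normalized so each modality's weights sum to 1.
#'
#' @param b Coefficient array, freq x lag x channel x m — e.g.
#'   `model$coefficients` from [npls_fit()] or any 4-way array.
#' @return An object of class `influence_profile`: a list of non-negative
#'   weight vectors `frequency`, `temporal`, `spatial`, each summing to 1.
#' @export
modality_influence <- function(b) {
  if (inherits(b, "npls_model")) b <- b$coefficients
  stopifnot(length(dim(b)) == 4L)
  ab <- abs(b)
  tot <- sum(ab)
  if (tot == 0) stop("all-zero coefficients have no influence profile",
                     call. = FALSE)
  norm1 <- function(v) v / sum(v)
  structure(
    list(frequency = norm1(apply(ab, 1L, sum)),
         temporal = norm1(apply(ab, 2L, sum)),
         spatial = norm1(apply(ab, 3L, sum))),
    class = "influence_profile"
  )
}

#' @export
print.influence_profile <- function(x, ...) {
  cat(sprintf(
    "<influence_profile> %d frequency, %d temporal, %d spatial weights\n",
    length(x$frequency), length(x$temporal), length(x$spatial)))
  invisible(x)
}

#' @rdname modality_influence
#' @param x An `influence_profile`.
#' @param ... Unused.
#' @method tidy influence_profile
#' @export
tidy.influence_profile <- function(x, ...) {
  dplyr::bind_rows(lapply(c("frequency", "temporal", "spatial"), function(mod) {
    tibble::tibble(modality = mod, index = seq_along(x[[mod]]),
                   weight = x[[mod]])
  }))
}

#' One-way ANOVA comparison of per-recording criterion values
#'
#' Thin evaluation helper: given per-recording values of one criterion for
#' several methods, fits `aov(value ~ method)` and reports the F-test
#' p-value and its significance at the given level.
#'
#' @param data A data frame with columns `method` and `value`.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble with `p_value` and `significant`.
#' @export
compare_methods_anova <- function(data, alpha = 0.05) {
  stopifnot(all(c("method", "value") %in% names(data)))
  fit <- stats::aov(value ~ method, data = transform(data, method = factor(method)))
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tibble::tibble(p_value = p, significant = p < alpha)
}
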