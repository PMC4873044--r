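#' Feature-extraction configuration
#'
#' Parameters for mapping a multichannel recording to the 4-way feature tensor
#' used by all decoders: each 1 s epoch of signal ending at a prediction time
#' is transformed with a complex Morlet continuous wavelet transform (CWT),
#' log-modulus taken, and averaged down to a small number of temporal bins,
#' giving a frequency x time-lag x channel cube per epoch.
#'
#' The mother wavelet is the complex Morlet
#' \deqn{\psi(t) = (\pi f_b)^{-1/2} \exp(2\pi i f_c t) \exp(-t^2/f_b),}
#' with bandwidth parameter `morlet_fb` and center frequency `morlet_fc`
#' (dimensionless; the kernel analysing frequency `f` is \eqn{\psi(t/a)/a} with
#' scale \eqn{a = f_c/f}, L1-normalized). The defaults (`fb = 2`, `fc = 1`)
#' make adjacent 10 Hz bins clearly resolvable within a 1 s epoch at the low
#' end of the default grid while keeping the kernel short relative to the
#' epoch.
#'
#' @param epoch_length Epoch length \eqn{\Delta\tau} in seconds (default 1).
#' @param epoch_step Shift \eqn{\Delta t} between consecutive epochs in
#'   seconds (default 0.1).
#' @param freq_grid Analysis frequencies in Hz, strictly increasing, all below
#'   the Nyquist frequency (default 10, 20, ..., 150).
#' @param n_time_bins Number of temporal bins each epoch is decimated to
#'   (default 10); must divide the per-epoch sample count.
#' @param sampling_rate Recording sampling rate in Hz (default 1000).
#' @param log_floor Positive floor \eqn{\epsilon} applied inside the
#'   log-modulus so an all-zero epoch maps to `log(log_floor)` (default 1e-12).
#' @param morlet_fb,morlet_fc Morlet bandwidth and center-frequency parameters.
#' @param artifact_filter Optional hook applied to the raw recording before
#'   epoching (a function `matrix -> matrix`, channels x samples); default
#'   `identity`.
#'
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(epoch_length = 1,
                           epoch_step = 0.1,
                           freq_grid = seq(10, 150, by = 10),
                           n_time_bins = 10,
                           sampling_rate = 1000,
                           log_floor = 1e-12,
                           morlet_fb = 2,
                           morlet_fc = 1,
                           artifact_filter = identity) {
  stopifnot(
    epoch_length > 0, epoch_step > 0,
    length(freq_grid) >= 1, all(diff(freq_grid) > 0),
    all(freq_grid < sampling_rate / 2),
    n_time_bins >= 1, log_floor > 0,
    morlet_fb > 0, morlet_fc > 0,
    is.function(artifact_filter)
  )
  n_samp <- round(epoch_length * sampling_rate)
  if (n_samp %% n_time_bins != 0) {
    stop("n_time_bins must divide round(epoch_length * sampling_rate)",
         call. = FALSE)
  }
  structure(
    list(
      epoch_length = epoch_length, epoch_step = epoch_step,
      freq_grid = freq_grid, n_time_bins = n_time_bins,
      sampling_rate = sampling_rate, log_floor = log_floor,
      morlet_fb = morlet_fb, morlet_fc = morlet_fc,
      artifact_filter = artifact_filter
    ),
    class = "feature_config"
  )
}

# Sampled complex Morlet kernel for analysis frequency f at sampling rate fs,
# truncated at 5 time-domain standard deviations, L1-normalized.
morlet_kernel <- function(f, fs, fb, fc) {
  a <- fc / f                       # scale, in seconds
  sd_t <- a * sqrt(fb / 2)          # time-domain std of the envelope
  half <- max(1L, ceiling(5 * sd_t * fs))
  t <- (-half:half) / fs
  psi <- (pi * fb)^(-0.5) * exp(2i * pi * fc * t / a) * exp(-(t / a)^2 / fb)
  psi / sum(Mod(psi))
}

#' Morlet log-modulus features for one epoch
#'
#' Computes, for each channel, the continuous wavelet transform of the epoch
#' with a complex Morlet wavelet at every frequency of `cfg$freq_grid`
#' (zero-padded convolution, so edge samples see an implicitly zero-extended
#' signal), then returns the log of the modulus floored at `cfg$log_floor`.
#'
#' @param epoch_signal Numeric matrix, channels x samples; the sample count
#'   must equal `round(cfg$epoch_length * cfg$sampling_rate)`.
#' @param cfg A [feature_config()].
#' @return A 3-way array, frequencies x samples x channels, with entries
#'   \eqn{\log(\max(|CWT|, \epsilon))}.
#' @export
morlet_epoch_features <- function(epoch_signal, cfg) {
  epoch_signal <- as.matrix(epoch_signal)
  assert_finite(epoch_signal, "epoch signal")
  n_samp <- round(cfg$epoch_length * cfg$sampling_rate)
  if (ncol(epoch_signal) != n_samp) {
    stop(sprintf("epoch must have exactly %d samples per channel, got %d",
                 n_samp, ncol(epoch_signal)), call. = FALSE)
  }
  n_ch <- nrow(epoch_signal)
  n_fr <- length(cfg$freq_grid)
  out <- array(NA_real_, dim = c(n_fr, n_samp, n_ch))
  for (k in seq_len(n_fr)) {
    ker <- morlet_kernel(cfg$freq_grid[k], cfg$sampling_rate,
                         cfg$morlet_fb, cfg$morlet_fc)
    half <- (length(ker) - 1L) %/% 2L
    n_fft <- n_samp + length(ker) - 1L
    kf <- stats::fft(c(ker, rep(0, n_fft - length(ker))))
    for (c in seq_len(n_ch)) {
      xf <- stats::fft(c(epoch_signal[c, ], rep(0, n_fft - n_samp)))
      full <- stats::fft(xf * kf, inverse = TRUE) / n_fft
      cwt <- full[(half + 1L):(half + n_samp)]
      out[k, , c] <- log(pmax(Mod(cwt), cfg$log_floor))
    }
  }
  out
}

#' Decimate the temporal axis of a feature cube by block averaging
#'
#' Averages contiguous, non-overlapping blocks of samples so that a
#' frequencies x samples x channels cube becomes frequencies x n_bins x
#' channels; with 1000 samples and 10 bins this is the 100-fold temporal
#' decimation of the standard extraction pipeline.
#'
#' @param cube 3-way array, frequencies x samples x channels.
#' @param n_bins Number of output bins; must divide the sample count.
#' @return 3-way array, frequencies x n_bins x channels.
#' @export
decimate_temporal <- function(cube, n_bins) {
  d <- dim(cube)
  stopifnot(length(d) == 3L)
  if (d[2L] %% n_bins != 0) {
    stop(sprintf("sample count %d is not divisible by n_bins = %d",
                 d[2L], n_bins), call. = FALSE)
  }
  block <- d[2L] %/% n_bins
  out <- array(0, dim = c(d[1L], n_bins, d[3L]))
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1L) * block + 1L):(b * block)
    out[, b, ] <- apply(cube[, idx, , drop = FALSE], c(1L, 3L), mean)
  }
  out
}

#' Build the aligned epoch feature tensor and response matrix
#'
#' Slides a window of length \eqn{\Delta\tau} over the recording with step
#' \eqn{\Delta t}: epochs end at \eqn{t_i = \Delta\tau + i\,\Delta t},
#' \eqn{i = 0, \dots, N-1}, \eqn{N = \lfloor (T-\Delta\tau)/\Delta t \rfloor + 1}.
#' Each epoch is mapped by [morlet_epoch_features()] and
#' [decimate_temporal()]; the response row is the trajectory sampled
#' (nearest neighbour in time) at the epoch end, so features are causal with
#' respect to the predicted position.
#'
#' @param recording Numeric matrix, channels x samples, covering `[0, T]`.
#' @param trajectory A data frame with columns `time, x, y, z` (or a numeric
#'   matrix with a `times` attribute) covering the epoch-end times.
#' @param cfg A [feature_config()].
#' @return A list with `tensor` (an `epoch_tensor`: N x freq x lag x channel
#'   array plus axis labels) and `trajectory` (tibble `time, x, y, z` sampled
#'   at the epoch ends).
#' @export
build_epoch_tensor <- function(recording, trajectory, cfg) {
  recording <- as.matrix(recording)
  assert_finite(recording, "recording")
  recording <- cfg$artifact_filter(recording)
  fs <- cfg$sampling_rate
  n_samp_epoch <- round(cfg$epoch_length * fs)
  total <- ncol(recording)
  t_end <- total / fs
  if (t_end < cfg$epoch_length - 1e-9) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  n_epochs <- floor((t_end - cfg$epoch_length) / cfg$epoch_step + 1e-9) + 1L
  epoch_times <- cfg$epoch_length + (seq_len(n_epochs) - 1L) * cfg$epoch_step

  ym <- traj_matrix(trajectory)
  tt <- traj_times(trajectory)
  if (is.null(tt)) stop("trajectory must carry times", call. = FALSE)
  if (max(epoch_times) > max(tt) + 1e-9 || min(epoch_times) < min(tt) - 1e-9) {
    stop("trajectory does not cover the epoch end-times", call. = FALSE)
  }

  n_fr <- length(cfg$freq_grid)
  n_ch <- nrow(recording)
  values <- array(NA_real_,
                  dim = c(n_epochs, n_fr, cfg$n_time_bins, n_ch))
  resp <- matrix(NA_real_, n_epochs, ncol(ym))
  for (i in seq_len(n_epochs)) {
    last <- round(epoch_times[i] * fs)
    idx <- (last - n_samp_epoch + 1L):last
    cube <- morlet_epoch_features(recording[, idx, drop = FALSE], cfg)
    values[i, , , ] <- decimate_temporal(cube, cfg$n_time_bins)
    resp[i, ] <- ym[which.min(abs(tt - epoch_times[i])), ]
  }

  tensor <- epoch_tensor(values, epoch_times = epoch_times,
                         freq_hz = cfg$freq_grid,
                         lag_s = (seq_len(cfg$n_time_bins) - 0.5) *
                           cfg$epoch_length / cfg$n_time_bins - cfg$epoch_length,
                         channels = seq_len(n_ch))
  traj <- tibble::tibble(time = epoch_times,
                         x = resp[, 1], y = resp[, 2], z = resp[, 3])
  list(tensor = tensor, trajectory = traj)
}

#' Construct an epoch feature tensor object
#'
#' A light container for the 4-way observations x frequency x time-lag x
#' channel feature block with its axis labels.
#'
#' @param values 4-way numeric array (N x freq x lag x channel), all finite.
#' @param epoch_times Epoch end-times in seconds, strictly increasing.
#' @param freq_hz,lag_s,channels Axis labels.
#' @return An object of class `epoch_tensor`.
#' @export
epoch_tensor <- function(values, epoch_times = NULL, freq_hz = NULL,
                         lag_s = NULL, channels = NULL) {
  stopifnot(length(dim(values)) == 4L)
  assert_finite(values, "feature tensor")
  d <- dim(values)
  if (is.null(epoch_times)) epoch_times <- seq_len(d[1L])
  stopifnot(length(epoch_times) == d[1L], all(diff(epoch_times) > 0))
  structure(
    list(values = values, epoch_times = as.numeric(epoch_times),
         freq_hz = if (is.null(freq_hz)) seq_len(d[2L]) else freq_hz,
         lag_s = if (is.null(lag_s)) seq_len(d[3L]) else lag_s,
         channels = if (is.null(channels)) seq_len(d[4L]) else channels),
    class = "epoch_tensor"
  )
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<epoch_tensor> %d epochs x %d frequencies x %d time bins x %d channels\n",
    d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

#' @export
dim.epoch_tensor <- function(x) dim(x$values)

# Accept either an epoch_tensor or a bare 4-way array everywhere downstream.
tensor_values <- function(x) {
  if (inherits(x, "epoch_tensor")) x$values else {
    stopifnot(length(dim(x)) == 4L)
    x
  }
}
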