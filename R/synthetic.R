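#' Configuration for the synthetic data generators
#'
#' The generators emulate the statistical structure the decoders assume: a
#' slow 3D trajectory, and a 4-way feature tensor carrying a linear rank-R
#' relationship to it under additive AR(1) noise along epochs (plus,
#' optionally, a raw band-modulated oscillatory recording for end-to-end
#' feature-extraction tests).
#'
#' @param n_epochs Number of epochs N (>= 20).
#' @param dt Epoch step in seconds (default 0.1).
#' @param cutoff_hz Trajectory low-pass cutoff in Hz (default 1; reaching
#'   movements are slow relative to the 10 Hz epoch rate). Must be below the
#'   Nyquist frequency `1/(2 dt)`.
#' @param n_planted Number R of planted rank-one factors (default 2).
#' @param dims Feature-mode dimensions `c(freq, lag, channel)` (default
#'   `c(15, 10, 64)`, the dimensions of the standard extraction pipeline).
#' @param snr Ratio of signal to noise variance in the tensor (default 10).
#' @param noise_ar AR(1) coefficient of the epoch-level noise in `[0, 1)`
#'   (default 0.3); low values give temporally rough noise, which is what the
#'   smoothness penalties are designed to suppress.
#' @param raw Options for [gen_raw_recording()]: a list with `channels`,
#'   `sampling_rate` (Hz), `carrier_hz` (one band per coordinate),
#'   `depth` (modulation depth), `noise` (background 1/f noise scale),
#'   `n_informative` (leading channels carrying the modulated carriers).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_epochs = 500,
                             dt = 0.1,
                             cutoff_hz = 1,
                             n_planted = 2,
                             dims = c(15, 10, 64),
                             snr = 10,
                             noise_ar = 0.3,
                             raw = list(channels = 8, sampling_rate = 200,
                                        carrier_hz = c(20, 40, 60),
                                        depth = 0.5, noise = 0.2,
                                        n_informative = 6)) {
  stopifnot(
    n_epochs >= 20, dt > 0, cutoff_hz > 0, cutoff_hz < 0.5 / dt,
    n_planted >= 1, length(dims) == 3L, all(dims >= 1),
    snr > 0, noise_ar >= 0, noise_ar < 1
  )
  structure(
    list(n_epochs = as.integer(n_epochs), dt = dt, cutoff_hz = cutoff_hz,
         n_planted = as.integer(n_planted), dims = as.integer(dims),
         snr = snr, noise_ar = noise_ar, raw = raw),
    class = "synthetic_config"
  )
}

#' Named synthetic study conditions
#'
#' Two fixed families used throughout the test-bench:
#' * `"recovery-easy"` — N = 300 epochs, modes 6 x 5 x 8, R = 3 planted
#'   factors, SNR 10, noise AR coefficient 0.3: factor recovery and held-out
#'   accuracy should be comfortable for a correct NPLS implementation.
#' * `"noisy-smooth"` — N = 2000 epochs, modes 6 x 5 x 8, R = 3, per-cell
#'   SNR 0.02, noise AR coefficient 0.2: a smooth trajectory buried in
#'   temporally rough noise. The per-cell SNR is deliberately far below 1:
#'   scores aggregate the 240 feature cells, so the score-level
#'   signal-to-noise ratio is about `snr * p / R` (~1.6 here), putting
#'   held-out correlation near 0.7-0.8 — the range typical of real epidural
#'   decoding, and the regime where the smoothness penalties reduce MADE
#'   while leaving correlation essentially unchanged. A per-cell SNR near 1
#'   would make decoding essentially noiseless (r > 0.99) and leave nothing
#'   for a smoothness penalty to do.
#'
#' @param name Preset name.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("recovery-easy", "noisy-smooth")) {
  name <- match.arg(name)
  switch(name,
    "recovery-easy" = synthetic_config(
      n_epochs = 300, dims = c(6, 5, 8), n_planted = 3,
      snr = 10, noise_ar = 0.3),
    "noisy-smooth" = synthetic_config(
      n_epochs = 2000, dims = c(6, 5, 8), n_planted = 3,
      snr = 0.02, noise_ar = 0.2)
  )
}

#' Generate a smooth 3D trajectory
#'
#' Each coordinate is Gaussian white noise brick-wall low-pass filtered in the
#' Fourier domain below `cutoff_hz`, then standardized to zero mean and unit
#' variance. A pure function of `(cfg, seed)`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return A tibble `time, x, y, z` with `time = (0:(N-1)) * dt`.
#' @export
gen_trajectory <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_epochs
  with_seed(seed, {
    ym <- sapply(1:3, function(j) {
      e <- stats::rnorm(n)
      lowpass_fft(e, dt = cfg$dt, cutoff = cfg$cutoff_hz)
    })
  })
  ym <- scale(ym)  # zero mean, unit variance per coordinate
  tibble::tibble(time = (seq_len(n) - 1L) * cfg$dt,
                 x = ym[, 1], y = ym[, 2], z = ym[, 3])
}

# Brick-wall low-pass in the Fourier domain: zero every Fourier-frequency bin
# strictly above `cutoff` Hz (keeping conjugate symmetry), inverse transform.
lowpass_fft <- function(x, dt, cutoff) {
  n <- length(x)
  freqs <- c(0, seq_len(n - 1L)) / (n * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)  # two-sided frequency axis
  xf <- stats::fft(x)
  xf[freqs > cutoff] <- 0
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Generate a feature tensor linearly driven by a trajectory
#'
#' Builds \eqn{X = \sum_{r=1}^R c_r \circ (w_{1r} \circ w_{2r} \circ w_{3r})
#' + \mathrm{noise}}: the planted projectors are orthonormal within each mode
#' (QR factor of a seeded Gaussian draw, so the factors are identifiable),
#' the factor streams \eqn{c_r} are fixed linear
#' combinations of the trajectory coordinates, and the noise is AR(1) along
#' epochs (independent across feature cells) scaled so that the ratio of
#' signal variance to stationary noise variance equals `cfg$snr`.
#'
#' @param traj A trajectory from [gen_trajectory()] (tibble or N x 3 matrix).
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return An `epoch_tensor` with an extra attribute `planted` (the list of
#'   projectors and factor streams used).
#' @export
gen_feature_tensor <- function(traj, cfg, seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ym <- traj_matrix(traj)
  n <- nrow(ym)
  r <- cfg$n_planted
  if (r > min(cfg$dims)) {
    stop("n_planted exceeds a feature-mode dimension", call. = FALSE)
  }
  p <- prod(cfg$dims)
  with_seed(seed, {
    # orthonormal projectors within each mode (QR of a Gaussian draw): makes
    # the planted factors identifiable, so noise-free recovery is exact
    ortho <- function(k) qr.Q(qr(matrix(stats::rnorm(k * r), k, r)))
    w1 <- ortho(cfg$dims[1L])
    w2 <- ortho(cfg$dims[2L])
    w3 <- ortho(cfg$dims[3L])
    mix <- matrix(stats::rnorm(3 * r), 3, r)
    mix <- if (r <= 3) {
      qr.Q(qr(mix))  # orthonormal columns: R = 3 spans all coordinates
    } else {
      sweep(mix, 2L, sqrt(colSums(mix^2)), `/`)
    }
    cs <- ym %*% mix                      # N x R factor streams
    wv <- sapply(seq_len(r), function(i) vec_rank1(w1[, i], w2[, i], w3[, i]))
    sig <- cs %*% t(wv)                   # N x p
    var_sig <- stats::var(as.vector(sig))
    a <- cfg$noise_ar
    sd_innov <- sqrt(var_sig / cfg$snr * (1 - a^2))
    eps <- matrix(stats::rnorm(n * p, sd = sd_innov), n, p)
    noise <- if (a > 0) {
      apply(eps, 2L, function(e) as.numeric(stats::filter(e, a, method = "recursive")))
    } else {
      eps
    }
    xm <- sig + noise
  })
  out <- epoch_tensor(fold_obs(xm, cfg$dims),
                      epoch_times = (seq_len(n) - 1L) * cfg$dt + cfg$dt)
  attr(out, "planted") <- list(w1 = w1, w2 = w2, w3 = w3, mix = mix,
                               streams = cs)
  out
}

#' Generate a raw band-modulated multichannel recording
#'
#' An end-to-end input for the feature-extraction pipeline: each informative
#' channel is \eqn{\sum_b (1 + d\, m_b(t)) \sin(2\pi f_b t + \phi)} plus 1/f
#' background noise, where \eqn{m_b(t)} is trajectory coordinate `b`
#' interpolated to the recording rate; the remaining channels carry noise
#' only. The recording spans `[0, max(traj$time)]` seconds.
#'
#' @param traj A trajectory tibble with a `time` column.
#' @param cfg A [synthetic_config()]; `cfg$raw` holds the channel count,
#'   sampling rate, carrier bands, modulation depth and noise scale.
#' @param seed Integer seed.
#' @return A channels x samples numeric matrix with attribute
#'   `sampling_rate`.
#' @export
gen_raw_recording <- function(traj, cfg, seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  rw <- cfg$raw
  fs <- rw$sampling_rate
  if (fs < 2 * max(rw$carrier_hz)) {
    stop("sampling rate below twice the top carrier band", call. = FALSE)
  }
  tt <- traj_times(traj)
  ym <- traj_matrix(traj)
  dur <- max(tt)
  n_samp <- round(dur * fs)
  t_grid <- seq_len(n_samp) / fs
  mods <- sapply(seq_len(ncol(ym)), function(j) {
    stats::approx(tt, ym[, j], xout = t_grid, rule = 2)$y
  })
  with_seed(seed, {
    rec <- matrix(0, rw$channels, n_samp)
    for (ch in seq_len(rw$channels)) {
      if (ch <= rw$n_informative) {
        for (b in seq_along(rw$carrier_hz)) {
          phi <- stats::runif(1, 0, 2 * pi)
          mb <- mods[, ((b - 1L) %% ncol(mods)) + 1L]
          rec[ch, ] <- rec[ch, ] +
            (1 + rw$depth * mb) * sin(2 * pi * rw$carrier_hz[b] * t_grid + phi)
        }
      }
      rec[ch, ] <- rec[ch, ] + rw$noise * pink_noise(n_samp)
    }
    rec
  })
  attr(rec, "sampling_rate") <- fs
  rec
}

# 1/f-shaped Gaussian noise, unit variance.
pink_noise <- function(n) {
  xf <- stats::fft(stats::rnorm(n))
  k <- c(1, seq_len(n - 1L))
  k <- pmin(k, n - k + 1)          # symmetric frequency index, >= 1
  xf <- xf / sqrt(k)
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  as.numeric(scale(x))
}
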