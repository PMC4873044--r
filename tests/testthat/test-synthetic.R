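cfg_small <- synthetic_config(n_epochs = 200, dims = c(6, 5, 8),
                              n_planted = 3)

test_that("generators are pure functions of (config, seed)", {
  t1 <- gen_trajectory(cfg_small, 42)
  t2 <- gen_trajectory(cfg_small, 42)
  expect_identical(t1, t2)
  x1 <- gen_feature_tensor(t1, cfg_small, 43)
  x2 <- gen_feature_tensor(t1, cfg_small, 43)
  expect_identical(x1$values, x2$values)
  r1 <- gen_raw_recording(t1, cfg_small, 44)
  r2 <- gen_raw_recording(t1, cfg_small, 44)
  expect_identical(r1, r2)
  expect_false(identical(gen_trajectory(cfg_small, 1)$x,
                         gen_trajectory(cfg_small, 2)$x))
  # the caller's RNG stream is untouched
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(gen_trajectory(cfg_small, 9)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("trajectories are standardized and spectrally band-limited", {
  traj <- gen_trajectory(cfg_small, 5)
  ym <- as.matrix(traj[c("x", "y", "z")])
  expect_equal(dim(ym), c(200, 3))
  expect_lt(max(abs(colMeans(ym))), 1e-10)
  expect_equal(unname(apply(ym, 2, sd)), rep(1, 3), tolerance = 1e-10)
  # periodogram power above the cutoff < 1% per coordinate
  n <- nrow(ym); dt <- cfg_small$dt
  freqs <- (0:(n - 1)) / (n * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)
  for (j in 1:3) {
    pgram <- Mod(fft(ym[, j]))^2
    frac <- sum(pgram[freqs > cfg_small$cutoff_hz]) / sum(pgram[-1])
    expect_lt(frac, 0.01)
  }
})

test_that("feature tensors have the configured shape and planted structure", {
  cfg_def <- synthetic_config(n_epochs = 30)
  traj <- gen_trajectory(cfg_def, 6)
  tens <- gen_feature_tensor(traj, cfg_def, 7)
  expect_equal(dim(tens$values), c(30, 15, 10, 64))

  expect_error(
    gen_feature_tensor(traj, synthetic_config(n_epochs = 30, dims = c(3, 3, 3),
                                              n_planted = 4), 8),
    "exceeds")
})

test_that("noise-free tensors are decoded perfectly and projectors recovered", {
  cfg_clean <- synthetic_config(n_epochs = 150, dims = c(6, 5, 8),
                                n_planted = 3, snr = 1e12, noise_ar = 0)
  traj <- gen_trajectory(cfg_clean, 10)
  tens <- gen_feature_tensor(traj, cfg_clean, 11)
  m <- npls_fit(tens, traj, 3)
  pred <- predict(m, tens)
  ym <- as.matrix(traj[c("x", "y", "z")])
  r_train <- vapply(1:3, function(j) cor(ym[, j], pred[, j]), numeric(1))
  expect_true(all(r_train > 1 - 1e-6))

  planted <- attr(tens, "planted")
  # match each planted factor to its best-aligned fitted factor per mode
  for (r in 1:3) {
    cos1 <- max(abs(crossprod(planted$w1[, r], m$W1)))
    cos3 <- max(abs(crossprod(planted$w3[, r], m$W3)))
    expect_gt(cos1, 0.999)
    expect_gt(cos3, 0.999)
  }
})

test_that("projector recovery holds on average at SNR 10 across seeds", {
  cfg <- synthetic_config(n_epochs = 200, dims = c(6, 5, 8), n_planted = 3,
                          snr = 10)
  coss <- c()
  for (s in 1:10) {
    traj <- gen_trajectory(cfg, 500 + s)
    tens <- gen_feature_tensor(traj, cfg, 600 + s)
    m <- npls_fit(tens, traj, 3)
    planted <- attr(tens, "planted")
    for (r in 1:3) {
      coss <- c(coss,
                max(abs(crossprod(planted$w1[, r], m$W1))),
                max(abs(crossprod(planted$w2[, r], m$W2))),
                max(abs(crossprod(planted$w3[, r], m$W3))))
    }
  }
  expect_gte(mean(coss), 0.9)
})

test_that("realized tensor SNR matches the configured value within 10%", {
  cfg <- synthetic_config(n_epochs = 2000, dims = c(6, 5, 8), n_planted = 3,
                          snr = 2, noise_ar = 0.2)
  traj <- gen_trajectory(cfg, 20)
  tens <- gen_feature_tensor(traj, cfg, 21)
  planted <- attr(tens, "planted")
  wv <- sapply(1:3, function(i) {
    as.vector(outer(outer(planted$w1[, i], planted$w2[, i]), planted$w3[, i]))
  })
  sig <- planted$streams %*% t(wv)
  noise <- matrix(tens$values, 2000) - sig
  snr_hat <- var(as.vector(sig)) / var(as.vector(noise))
  expect_lt(abs(snr_hat - 2) / 2, 0.1)
})

test_that("raw recordings have the right shape and band-power coupling", {
  cfg <- synthetic_config(
    n_epochs = 400, dims = c(6, 5, 8), n_planted = 3,
    raw = list(channels = 6, sampling_rate = 200, carrier_hz = c(20, 40, 60),
               depth = 0.8, noise = 0.05, n_informative = 4))
  traj <- gen_trajectory(cfg, 30)
  rec <- gen_raw_recording(traj, cfg, 31)
  expect_equal(dim(rec), c(6, round(max(traj$time) * 200)))
  expect_true(all(is.finite(rec)))

  # band power of an informative channel at its carrier tracks the coordinate
  fs <- 200
  win <- fs            # 1 s windows at the trajectory rate grid
  times <- traj$time[traj$time >= 1]
  bp <- vapply(times, function(t0) {
    idx <- (round((t0 - 1) * fs) + 1):round(t0 * fs)
    seg <- rec[1, idx]
    sp <- Mod(fft(seg))^2
    f_axis <- (seq_along(seg) - 1) * fs / length(seg)
    sum(sp[abs(f_axis - 20) <= 2])
  }, numeric(1))
  m1 <- approx(traj$time, traj$x, xout = times - 0.5, rule = 2)$y
  expect_gt(cor(bp, m1), 0.5)
})

test_that("features from a raw recording support accurate decoding end-to-end", {
  cfg <- synthetic_config(
    n_epochs = 600, dims = c(6, 5, 8), n_planted = 3,
    raw = list(channels = 8, sampling_rate = 200, carrier_hz = c(20, 40, 60),
               depth = 0.5, noise = 0.2, n_informative = 6))
  traj <- gen_trajectory(cfg, 40)
  rec <- gen_raw_recording(traj, cfg, 41)
  fcfg <- feature_config(sampling_rate = 200, freq_grid = seq(10, 90, by = 10),
                         n_time_bins = 10)
  built <- build_epoch_tensor(rec, traj, fcfg)
  sp <- chronological_split(built$tensor, built$trajectory, 0.7)
  ecfg <- experiment_config("npls", f_grid = 1:10, folds = 5)
  sel <- crossval_select(sp$train$x, sp$train$y, ecfg)
  m <- npls_fit(sp$train$x, sp$train$y, sel$n_factors)
  pred <- predict(m, sp$test$x)
  r <- mean(vapply(1:3, function(j) cor(sp$test$y[, j], pred[, j]), numeric(1)))
  expect_gte(r, 0.8)
})
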