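# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain matrix algebra, literal textbook
# recursions, per-window model fits.

# Multi-restart alternating least squares for the dominant rank-one
# approximation of a 3-way array; returns the best |objective| found.
als_rank1_oracle <- function(z, n_restarts = 100, n_iter = 200) {
  d <- dim(z)
  m1 <- matrix(z, d[1], d[2] * d[3])
  m2 <- matrix(aperm(z, c(2, 1, 3)), d[2], d[1] * d[3])
  m3 <- matrix(aperm(z, c(3, 1, 2)), d[3], d[1] * d[2])
  best <- -Inf
  for (r in seq_len(n_restarts)) {
    w1 <- rnorm(d[1]); w1 <- w1 / sqrt(sum(w1^2))
    w2 <- rnorm(d[2]); w2 <- w2 / sqrt(sum(w2^2))
    w3 <- rnorm(d[3]); w3 <- w3 / sqrt(sum(w3^2))
    for (it in seq_len(n_iter)) {
      w1 <- m1 %*% as.vector(outer(w2, w3)); w1 <- w1 / sqrt(sum(w1^2))
      w2 <- m2 %*% as.vector(outer(w1, w3)); w2 <- w2 / sqrt(sum(w2^2))
      w3 <- m3 %*% as.vector(outer(w1, w2)); w3 <- w3 / sqrt(sum(w3^2))
    }
    obj <- abs(sum(z * outer(outer(as.vector(w1), as.vector(w2)), as.vector(w3))))
    if (obj > best) best <- obj
  }
  best
}

# Bilinear NIPALS PLS2 regression (X deflated by t w', matching the matrix
# special case of the tri-linear decomposition), written directly in matrix
# form. Returns a closure that predicts new rows.
nipals_pls2_oracle <- function(x, y, n_factors, tol = 1e-10) {
  xm <- colMeans(x); ym <- colMeans(y)
  e <- sweep(x, 2, xm); fr <- sweep(y, 2, ym)
  n <- nrow(x); p <- ncol(x); m <- ncol(y)
  ws <- matrix(0, p, n_factors); qs <- matrix(0, m, n_factors)
  ts <- matrix(0, n, n_factors); cmat <- matrix(0, n_factors, m)
  for (f in seq_len(n_factors)) {
    sv <- svd(fr, nu = 1, nv = 0)
    u <- sv$u[, 1] * sv$d[1]
    t_old <- rep(0, n)
    for (it in 1:1000) {
      w <- crossprod(e, u); w <- w / sqrt(sum(w^2))
      tt <- as.vector(e %*% w)
      q <- crossprod(fr, tt); q <- q / sqrt(sum(q^2))
      u <- as.vector(fr %*% q)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) { t_old <- tt; break }
      t_old <- tt
    }
    ws[, f] <- w; qs[, f] <- q; ts[, f] <- t_old
    b <- qr.solve(ts[, 1:f, drop = FALSE], u)
    cmat[1:f, ] <- cmat[1:f, , drop = FALSE] + b %*% t(q)
    e <- e - t_old %*% t(w)
    fr <- fr - (ts[, 1:f, drop = FALSE] %*% b) %*% t(q)
  }
  function(xnew) {
    en <- sweep(xnew, 2, xm)
    tn <- matrix(0, nrow(xnew), n_factors)
    for (f in seq_len(n_factors)) {
      tn[, f] <- en %*% ws[, f]
      en <- en - tn[, f] %*% t(ws[, f])
    }
    sweep(tn %*% cmat, 2, ym, `+`)
  }
}

# Literal textbook Kalman filter loop over centered observations.
naive_kf_oracle <- function(a, h, w, q, x_centered, y0, p0) {
  n_steps <- nrow(x_centered)
  m <- ncol(a)
  out <- matrix(0, n_steps, m)
  y_hat <- y0; p <- p0
  for (k in seq_len(n_steps)) {
    y_prior <- a %*% y_hat
    p_prior <- a %*% p %*% t(a) + w
    kk <- p_prior %*% t(h) %*% solve(h %*% p_prior %*% t(h) + q)
    y_hat <- y_prior + kk %*% (x_centered[k, ] - h %*% y_prior)
    p <- (diag(m) - kk %*% h) %*% p_prior
    out[k, ] <- y_hat
  }
  out
}

# Degree-p polynomial fit over one window, evaluated at the window center,
# via lm() on the offset grid.
polyfit_center_oracle <- function(window_values, p) {
  l <- (length(window_values) - 1) / 2
  grid <- (-l):l
  fit <- lm(window_values ~ poly(grid, degree = p, raw = TRUE))
  unname(predict(fit, newdata = data.frame(grid = 0)))
}

# Direct time-domain convolution with the analytic complex Morlet kernel at
# one frequency (zero-extended signal), log-modulus floored.
direct_morlet_oracle <- function(sig, f, fs, fb, fc, eps) {
  a <- fc / f
  half <- max(1, ceiling(5 * a * sqrt(fb / 2) * fs))
  tt <- (-half:half) / fs
  psi <- (pi * fb)^(-0.5) * exp(2i * pi * fc * tt / a) * exp(-(tt / a)^2 / fb)
  psi <- psi / sum(Mod(psi))
  n <- length(sig)
  out <- complex(n)
  for (i in seq_len(n)) {
    js <- (i - half):(i + half)
    ok <- js >= 1 & js <= n
    out[i] <- sum(sig[js[ok]] * psi[length(psi) + 1 - which(ok)])
  }
  log(pmax(Mod(out), eps))
}

# Rank-one epoch tensor driven by a scalar stream: x_i = y_i * (a o b o c).
make_rank1_tensor <- function(yv, a, b, c3) {
  n <- length(yv)
  x <- array(0, c(n, length(a), length(b), length(c3)))
  cube <- outer(outer(a, b), c3)
  for (i in seq_len(n)) x[i, , , ] <- yv[i] * cube
  x
}
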