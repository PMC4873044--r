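test_that("rank_one_approx recovers exact rank-one structure", {
  a <- c(2, -1, 0.5); b <- c(1, 2, 3, 4); c3 <- c(0.3, -0.2, 1, 0, 2)
  r1 <- rank_one_approx(outer(outer(a, b), c3))
  expect_equal(abs(r1$w1), abs(a) / sqrt(sum(a^2)), tolerance = 1e-10)
  expect_equal(abs(r1$w2), abs(b) / sqrt(sum(b^2)), tolerance = 1e-10)
  expect_equal(abs(r1$w3), abs(c3) / sqrt(sum(c3^2)), tolerance = 1e-10)
  expect_equal(abs(r1$objective),
               sqrt(sum(a^2)) * sqrt(sum(b^2)) * sqrt(sum(c3^2)),
               tolerance = 1e-10)
  # sign convention
  expect_gt(r1$w1[1], 0); expect_gt(r1$w2[1], 0); expect_gt(r1$w3[1], 0)
})

test_that("rank_one_approx handles a single nonzero cell and zero input", {
  z <- array(0, c(3, 4, 5))
  z[2, 3, 4] <- -7
  r1 <- rank_one_approx(z)
  expect_equal(r1$w1, c(0, 1, 0))
  expect_equal(r1$w2, c(0, 0, 1, 0))
  expect_equal(r1$w3, c(0, 0, 0, 1, 0))
  expect_equal(abs(r1$objective), 7)
  expect_error(rank_one_approx(array(0, c(2, 2, 2))), "degenerate")
})

test_that("rank_one_approx matches a 100-restart ALS oracle on random blocks", {
  set.seed(101)
  for (rep in 1:3) {
    z <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
    r1 <- rank_one_approx(z)
    expect_equal(abs(r1$objective), als_rank1_oracle(z, 100), tolerance = 1e-6)
  }
})

test_that("noiseless rank-one data are fit perfectly with one factor", {
  set.seed(102)
  a <- rnorm(3); b <- rnorm(4); c3 <- rnorm(5)
  yv <- rnorm(40)
  x <- make_rank1_tensor(yv, a, b, c3)
  m <- npls_fit(x, matrix(yv), 1)
  pred <- predict(m, x)
  expect_lt(max(abs(pred - yv)), 1e-8)
  expect_gt(abs(sum(m$W1[, 1] * a / sqrt(sum(a^2)))), 1 - 1e-8)
  expect_gt(abs(sum(m$W2[, 1] * b / sqrt(sum(b^2)))), 1 - 1e-8)
  expect_gt(abs(sum(m$W3[, 1] * c3 / sqrt(sum(c3^2)))), 1 - 1e-8)
})

test_that("singleton lag/channel modes reproduce a matrix-PLS oracle", {
  set.seed(103)
  n <- 60; p <- 12
  x <- matrix(rnorm(n * p), n, p)
  y <- x %*% matrix(rnorm(p * 3) / 3, p, 3) + 0.3 * matrix(rnorm(n * 3), n, 3)
  xnew <- matrix(rnorm(20 * p), 20, p)
  for (f in 1:3) {
    m <- npls_fit(array(x, c(n, p, 1, 1)), y, f, tol = 1e-12)
    pred <- predict(m, array(xnew, c(20, p, 1, 1)))
    oracle <- nipals_pls2_oracle(x, y, f, tol = 1e-12)
    expect_lt(max(abs(pred - oracle(xnew))), 1e-8)
  }
})

test_that("held-out accuracy on the recovery-easy condition is high", {
  cfg <- synthetic_preset("recovery-easy")
  traj <- gen_trajectory(cfg, 0)
  tens <- gen_feature_tensor(traj, cfg, 1)
  sp <- chronological_split(tens, traj, 0.7)
  m <- npls_fit(sp$train$x, sp$train$y, cfg$n_planted)
  pred <- predict(m, sp$test$x)
  r <- mean(vapply(1:3, function(j) cor(sp$test$y[, j], pred[, j]), numeric(1)))
  expect_gte(r, 0.9)
})

test_that("prediction at the training mean returns the response mean", {
  set.seed(104)
  x <- array(rnorm(30 * 2 * 3 * 4), c(30, 2, 3, 4))
  y <- matrix(rnorm(90), 30, 3)
  m <- npls_fit(x, y, 2)
  mean_cube <- array(m$x_mean, c(1, 2, 3, 4))
  expect_equal(as.vector(predict(m, mean_cube)), as.vector(m$y_mean),
               tolerance = 1e-10)
})

test_that("sequential scores and materialized coefficients agree", {
  set.seed(105)
  x <- array(rnorm(40 * 3 * 4 * 5), c(40, 3, 4, 5))
  y <- matrix(rnorm(80), 40, 2)
  m <- npls_fit(x, y, 3)
  bmat <- matrix(m$coefficients, prod(m$dims), m$n_response)
  xnew <- array(rnorm(100 * 3 * 4 * 5), c(100, 3, 4, 5))
  p_seq <- predict(m, xnew)
  xc <- sweep(matrix(xnew, 100, prod(m$dims)), 2, m$x_mean)
  p_mat <- sweep(xc %*% bmat, 2, m$y_mean, `+`)
  expect_lt(max(abs(p_seq - p_mat)), 1e-10)
})

test_that("the coefficient map is linear and zero for a mean-only model", {
  set.seed(106)
  x <- array(rnorm(30 * 2 * 3 * 4), c(30, 2, 3, 4))
  y <- matrix(rnorm(60), 30, 2)
  m0 <- npls_fit(x, y, 0)
  expect_equal(m0$coefficients, array(0, c(2, 3, 4, 2)))
  expect_equal(predict(m0, x), matrix(m0$y_mean, 30, 2, byrow = TRUE))

  m <- npls_fit(x, y, 2)
  x1 <- array(rnorm(2 * 3 * 4), c(1, 2, 3, 4))
  x2 <- array(rnorm(2 * 3 * 4), c(1, 2, 3, 4))
  mean_cube <- array(m$x_mean, c(1, 2, 3, 4))
  al <- 1.7; be <- -0.6
  # combine centered inputs: alpha x1c + beta x2c (+ mean) must map to
  # alpha yhat1c + beta yhat2c (+ mean)
  comb <- array(al * (x1 - mean_cube) + be * (x2 - mean_cube), c(1, 2, 3, 4)) +
    mean_cube
  lhs <- predict(m, comb) - m$y_mean
  rhs <- al * (predict(m, x1) - m$y_mean) + be * (predict(m, x2) - m$y_mean)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("training RSS is non-increasing in the factor count", {
  set.seed(107)
  x <- array(rnorm(50 * 3 * 4 * 5), c(50, 3, 4, 5))
  y <- matrix(rnorm(150), 50, 3)
  m <- npls_fit(x, y, 6)
  expect_true(all(diff(m$rss) <= 1e-10))
})

test_that("factor extraction is nested and projectors obey norms and signs", {
  set.seed(108)
  x <- array(rnorm(50 * 3 * 4 * 5), c(50, 3, 4, 5))
  y <- matrix(rnorm(100), 50, 2)
  m <- npls_fit(x, y, 4)
  # greedy sequential extraction: a smaller fit is a prefix of a larger one,
  # and predicting with truncated factors equals the smaller fit's prediction
  m2 <- npls_fit(x, y, 2)
  expect_equal(m2$scores, m$scores[, 1:2], tolerance = 1e-10)
  expect_equal(m2$W1, m$W1[, 1:2], tolerance = 1e-10)
  xnew <- array(rnorm(10 * 3 * 4 * 5), c(10, 3, 4, 5))
  expect_equal(predict(m, xnew, n_factors = 2), predict(m2, xnew),
               tolerance = 1e-10)
  # each deflated residual is exactly orthogonal to its own factor's weights:
  # the same weight vector extracts a zero score from the deflated tensor
  e <- sweep(matrix(x, 50, 60), 2, m$x_mean)
  for (f in 1:4) {
    wvec <- as.vector(outer(outer(m$W1[, f], m$W2[, f]), m$W3[, f]))
    tf <- e %*% wvec
    expect_equal(as.vector(tf), m$scores[, f], tolerance = 1e-8)
    e <- e - tf %*% t(wvec)
    expect_lt(max(abs(e %*% wvec)), 1e-8)
  }
  for (f in 1:4) {
    for (w in list(m$W1[, f], m$W2[, f], m$W3[, f], m$Q[, f])) {
      expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-10)
      expect_gt(w[which(abs(w) > 1e-12)[1]], 0)
    }
  }
})

test_that("permuting channels permutes the channel projector identically", {
  set.seed(109)
  x <- array(rnorm(40 * 3 * 4 * 5), c(40, 3, 4, 5))
  y <- matrix(rnorm(80), 40, 2)
  perm <- c(4, 1, 5, 2, 3)
  m1 <- npls_fit(x, y, 2)
  m2 <- npls_fit(x[, , , perm], y, 2)
  # sign convention may flip a permuted projector; compare up to sign
  for (f in 1:2) {
    d <- min(max(abs(m2$W3[, f] - m1$W3[perm, f])),
             max(abs(m2$W3[, f] + m1$W3[perm, f])))
    expect_lt(d, 1e-8)
    expect_equal(abs(m2$W1[, f]), abs(m1$W1[, f]), tolerance = 1e-8)
  }
})

test_that("degenerate responses truncate the model with a warning", {
  set.seed(110)
  a <- rnorm(3); b <- rnorm(4); c3 <- rnorm(5)
  yv <- rnorm(30)
  x <- make_rank1_tensor(yv, a, b, c3)
  expect_warning(m <- npls_fit(x, matrix(yv), 3), "truncated|degenerate")
  expect_lt(m$n_factors, 3)
  expect_true(m$truncated)
})

test_that("tidiers return well-formed tibbles", {
  set.seed(111)
  x <- array(rnorm(30 * 2 * 3 * 4), c(30, 2, 3, 4))
  y <- matrix(rnorm(60), 30, 2)
  m <- npls_fit(x, y, 2)
  td <- tidy(m)
  expect_setequal(unique(td$modality),
                  c("frequency", "temporal", "spatial", "response"))
  expect_equal(nrow(td), 2 * (2 + 3 + 4 + 2))
  gl <- glance(m)
  expect_equal(gl$n_factors, 2L)
  expect_equal(gl$n_features, 24)
})
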