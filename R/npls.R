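#' Dominant rank-one approximation of a 3-way block
#'
#' Finds unit-norm vectors `w1, w2, w3` maximizing the contraction
#' \eqn{\langle Z, w_1 \circ w_2 \circ w_3 \rangle} by higher-order power
#' iteration (alternating contractions), deterministically initialized from
#' the dominant singular vectors of the three unfoldings. Each returned
#' vector is flipped so its first nonzero entry is positive; the signed
#' objective is returned alongside so callers can absorb the sign into a
#' score.
#'
#' @param z 3-way numeric array, finite and not all zero.
#' @param tol Convergence tolerance on the change of the stacked weight
#'   vector (default 1e-10).
#' @param max_iter Iteration cap (default 500).
#' @param n_restarts Number of alternating runs: the first starts from the
#'   higher-order SVD initialization, the rest from unit vectors drawn under
#'   a fixed internal seed (so the result is still deterministic). The best
#'   objective wins; restarts guard against local maxima of the non-convex
#'   objective on unstructured blocks (default 8). The NPLS inner loop uses a
#'   single run, where the contraction target is close to rank-one.
#' @return List with unit vectors `w1`, `w2`, `w3` and the signed `objective`
#'   \eqn{\langle Z, w_1 \circ w_2 \circ w_3\rangle}.
#' @export
rank_one_approx <- function(z, tol = 1e-10, max_iter = 500L, n_restarts = 8L) {
  d <- dim(z)
  stopifnot(length(d) == 3L, n_restarts >= 1L)
  assert_finite(z, "rank-one input")
  if (all(z == 0)) {
    stop("degenerate factor: all-zero block has no rank-one direction",
         call. = FALSE)
  }
  m1 <- matrix(z, d[1L], d[2L] * d[3L])
  m2 <- matrix(aperm(z, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
  m3 <- matrix(aperm(z, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
  dom_left <- function(m) {
    s <- svd(m, nu = 1L, nv = 0L)
    as.vector(s$u)
  }
  run_from <- function(w1, w2, w3) {
    for (it in seq_len(max_iter)) {
      prev <- c(w1, w2, w3)
      w1 <- m1 %*% as.vector(outer(w2, w3)); w1 <- w1 / l2(w1)
      w2 <- m2 %*% as.vector(outer(w1, w3)); w2 <- w2 / l2(w2)
      w3 <- m3 %*% as.vector(outer(w1, w2)); w3 <- w3 / l2(w3)
      w1 <- as.vector(w1); w2 <- as.vector(w2); w3 <- as.vector(w3)
      # signs may oscillate while the subspace is converged; compare up to sign
      if (min(l2(c(w1, w2, w3) - prev), l2(c(w1, w2, w3) + prev)) < tol) break
    }
    list(w1 = w1, w2 = w2, w3 = w3,
         obj = sum(z * outer(outer(w1, w2), w3)))
  }
  best <- run_from(dom_left(m1), dom_left(m2), dom_left(m3))
  if (n_restarts > 1L) {
    unit <- function(k) { v <- stats::rnorm(k); v / l2(v) }
    starts <- with_seed(20240601L, {
      lapply(seq_len(n_restarts - 1L), function(i) {
        list(unit(d[1L]), unit(d[2L]), unit(d[3L]))
      })
    })
    for (st in starts) {
      cand <- run_from(st[[1L]], st[[2L]], st[[3L]])
      if (abs(cand$obj) > abs(best$obj)) best <- cand
    }
  }
  s1 <- sign_flip(best$w1); s2 <- sign_flip(best$w2); s3 <- sign_flip(best$w3)
  list(w1 = s1 * best$w1, w2 = s2 * best$w2, w3 = s3 * best$w3,
       objective = s1 * s2 * s3 * best$obj)
}

#' Fit an N-way PLS regression between a 4-way tensor and a response matrix
#'
#' Tri-linear PLS in the tradition of Bro's tri-PLS: the centered tensor is
#' decomposed factor by factor as \eqn{X = \sum_f t_f \circ w_{1f} \circ
#' w_{2f} \circ w_{3f} + E} while the response is predicted through inner
#' regressions \eqn{u_f = T_f b_f} on the accumulated score matrix. Per
#' factor: the response-residual's dominant left singular vector seeds `u`;
#' the inner loop alternates (i) `Z = E' u` contracted over observations,
#' (ii) `(w1, w2, w3) = rank_one_approx(Z)`, (iii) score `t = E (w1 o w2 o
#' w3)`, (iv) response loading `q = F' t` normalized, (v) `u = F q`, until the
#' relative change of `t` falls below `tol`. `X` is deflated by the rank-one
#' component and `Y` by its prediction from the scores so far.
#'
#' @param x An `epoch_tensor` or 4-way array (N x I1 x I2 x I3).
#' @param y Response: data frame with a `time` column plus coordinates, or an
#'   N x m numeric matrix.
#' @param n_factors Number of latent factors F (0 gives the mean-only model).
#' @param center Center `x` and `y` by their column means before fitting
#'   (default TRUE). The penalized fits pass pre-centered augmented data with
#'   `center = FALSE` so the zero penalty rows stay exactly zero.
#' @param tol Inner-loop tolerance on the relative score change.
#' @param max_iter Inner-loop iteration cap.
#' @return An object of class `npls_model`: mode projectors `W1, W2, W3`
#'   (unit columns, first nonzero entry positive), response loadings `Q`,
#'   training scores `scores` (T) and response scores `u_scores` (U), inner
#'   coefficients `b` (list, factor f has length f), the F x m inner
#'   prediction map `inner_map`, centering means, and the materialized
#'   coefficient array `coefficients` (I1 x I2 x I3 x m).
#' @export
npls_fit <- function(x, y, n_factors, center = TRUE,
                     tol = 1e-8, max_iter = 500L) {
  xv <- tensor_values(x)
  ym <- traj_matrix(y)
  d <- dim(xv)
  n <- d[1L]
  stopifnot(nrow(ym) == n, ncol(ym) >= 1L, n_factors >= 0L)
  if (n_factors > 0L && n < n_factors + 1L) {
    stop("need at least n_factors + 1 observations", call. = FALSE)
  }
  xm <- unfold_obs(xv)
  xmean <- if (center) colMeans(xm) else rep(0, ncol(xm))
  ymean <- if (center) colMeans(ym) else rep(0, ncol(ym))
  e <- sweep(xm, 2L, xmean)
  f_res <- sweep(ym, 2L, ymean)

  dims3 <- d[2:4]
  m <- ncol(ym)
  w1s <- matrix(0, dims3[1L], n_factors)
  w2s <- matrix(0, dims3[2L], n_factors)
  w3s <- matrix(0, dims3[3L], n_factors)
  qs <- matrix(0, m, n_factors)
  tsc <- matrix(0, n, n_factors)
  usc <- matrix(0, n, n_factors)
  bs <- vector("list", n_factors)
  rss <- numeric(n_factors)
  n_done <- 0L

  for (f in seq_len(n_factors)) {
    sv <- svd(f_res, nu = 1L, nv = 0L)
    u <- as.vector(sv$u) * sv$d[1L]
    if (sv$d[1L] < 1e-12) {
      warning(sprintf("degenerate factor %d: response residual exhausted; model truncated", f))
      break
    }
    t_old <- rep(0, n)
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      zv <- crossprod(e, u)
      if (l2(zv) < 1e-14) { ok <- FALSE; break }
      r1 <- rank_one_approx(array(zv, dim = dims3), n_restarts = 1L)
      wvec <- vec_rank1(r1$w1, r1$w2, r1$w3)
      t_new <- as.vector(e %*% wvec)
      if (l2(t_new) < 1e-14) { ok <- FALSE; break }
      q <- as.vector(crossprod(f_res, t_new))
      q <- q / l2(q)
      sq <- sign_flip(q)
      q <- sq * q
      u <- as.vector(f_res %*% q)
      if (l2(t_new - t_old) < tol * max(l2(t_new), 1e-300)) {
        t_old <- t_new
        break
      }
      t_old <- t_new
    }
    if (!ok) {
      warning(sprintf("degenerate factor %d: zero contraction or score; model truncated", f))
      break
    }
    w1s[, f] <- r1$w1; w2s[, f] <- r1$w2; w3s[, f] <- r1$w3
    qs[, f] <- q
    tsc[, f] <- t_old
    usc[, f] <- u
    tf <- tsc[, seq_len(f), drop = FALSE]
    bs[[f]] <- as.vector(qr.solve(tf, u))
    e <- e - t_old %*% t(wvec)
    f_res <- f_res - (tf %*% bs[[f]]) %*% t(q)
    rss[f] <- sum(f_res^2)
    n_done <- f
  }

  if (n_done < n_factors) {
    w1s <- w1s[, seq_len(n_done), drop = FALSE]
    w2s <- w2s[, seq_len(n_done), drop = FALSE]
    w3s <- w3s[, seq_len(n_done), drop = FALSE]
    qs <- qs[, seq_len(n_done), drop = FALSE]
    tsc <- tsc[, seq_len(n_done), drop = FALSE]
    usc <- usc[, seq_len(n_done), drop = FALSE]
    bs <- bs[seq_len(n_done)]
    rss <- rss[seq_len(n_done)]
  }

  model <- structure(
    list(
      n_factors = n_done, dims = dims3, n_response = m,
      W1 = w1s, W2 = w2s, W3 = w3s, Q = qs,
      scores = tsc, u_scores = usc, b = bs,
      inner_map = inner_prediction_map(bs, qs, n_done, m),
      x_mean = xmean, y_mean = ymean,
      rss = rss, truncated = n_done < n_factors
    ),
    class = "npls_model"
  )
  model$coefficients <- materialize_coefficients(model)
  model
}

# F x m matrix M with Yhat = T %*% M: column contributions u_f q_f' with
# u_f = T[, 1:f] b_f, so M = sum_f pad(b_f) q_f'.
inner_prediction_map <- function(bs, qs, n_factors, m) {
  mm <- matrix(0, n_factors, m)
  for (f in seq_len(n_factors)) {
    bf <- c(bs[[f]], rep(0, n_factors - f))
    mm <- mm + bf %*% t(qs[, f])
  }
  mm
}

#' Predict a trajectory from a fitted NPLS model
#'
#' Centers the new tensor with the training means, extracts factor scores
#' sequentially with the stored projectors and the training deflation
#' structure, and maps them through the inner regressions and response
#' loadings. Equivalent (to numerical precision) to contracting the
#' materialized coefficient array with each centered observation and adding
#' the response mean.
#'
#' @param object A fitted `npls_model`.
#' @param x An `epoch_tensor` or 4-way array with the training feature-mode
#'   dimensions.
#' @param n_factors Use only the first `n_factors` factors (default: all);
#'   truncation equals refitting with the smaller factor count.
#' @param ... Unused.
#' @return Numeric matrix N x m of predicted responses.
#' @export
predict.npls_model <- function(object, x, n_factors = object$n_factors, ...) {
  xv <- tensor_values(x)
  d <- dim(xv)
  if (!all(d[2:4] == object$dims)) {
    stop("feature-mode dimensions do not match the fitted model", call. = FALSE)
  }
  stopifnot(n_factors >= 0L, n_factors <= object$n_factors)
  e <- sweep(unfold_obs(xv), 2L, object$x_mean)
  n <- d[1L]
  if (n_factors == 0L) {
    return(matrix(object$y_mean, n, object$n_response, byrow = TRUE))
  }
  tsc <- matrix(0, n, n_factors)
  for (f in seq_len(n_factors)) {
    wvec <- vec_rank1(object$W1[, f], object$W2[, f], object$W3[, f])
    tsc[, f] <- e %*% wvec
    e <- e - tsc[, f] %*% t(wvec)
  }
  mm <- inner_prediction_map(object$b[seq_len(n_factors)],
                             object$Q[, seq_len(n_factors), drop = FALSE],
                             n_factors, object$n_response)
  sweep(tsc %*% mm, 2L, object$y_mean, `+`)
}

#' Materialize the linear coefficient array of an NPLS model
#'
#' The sequential score pipeline is a linear map of the centered input, so the
#' whole model collapses to a coefficient block `B` with
#' \eqn{\hat y = \langle B, x - \bar x\rangle + \bar y}. The score functionals
#' are accumulated through the deflation recursion
#' \eqn{v_f = w_f - \sum_{g<f} (w_g^\top w_f)\, v_g} (the image of the
#' identity basis of the feature space under the pipeline), then combined with
#' the inner prediction map.
#'
#' @param model A fitted `npls_model`.
#' @return 4-way array I1 x I2 x I3 x m.
#' @export
materialize_coefficients <- function(model) {
  p <- prod(model$dims)
  m <- model$n_response
  nf <- model$n_factors
  if (nf == 0L) {
    return(array(0, dim = c(model$dims, m)))
  }
  wv <- sapply(seq_len(nf), function(f) {
    vec_rank1(model$W1[, f], model$W2[, f], model$W3[, f])
  })
  v <- matrix(0, p, nf)
  for (f in seq_len(nf)) {
    vf <- wv[, f]
    if (f > 1L) {
      g <- seq_len(f - 1L)
      vf <- vf - v[, g, drop = FALSE] %*% crossprod(wv[, g, drop = FALSE], wv[, f])
    }
    v[, f] <- vf
  }
  bmat <- v %*% model$inner_map
  array(as.vector(bmat), dim = c(model$dims, m))
}

#' @export
print.npls_model <- function(x, ...) {
  cat(sprintf(
    "<npls_model> %d factor(s); modes %s -> %d response column(s)%s\n",
    x$n_factors, paste(x$dims, collapse = " x "), x$n_response,
    if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' Broom-style tidiers for NPLS models
#'
#' `tidy()` returns one row per (factor, modality, index) with the projector
#' weight; `glance()` returns a one-row model summary.
#'
#' @param x,object A fitted `npls_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy npls_model
#' @export
tidy.npls_model <- function(x, ...) {
  if (x$n_factors == 0L) {
    return(tibble::tibble(factor = integer(), modality = character(),
                          index = integer(), weight = numeric()))
  }
  one <- function(w, modality) {
    do.call(rbind, lapply(seq_len(ncol(w)), function(f) {
      tibble::tibble(factor = f, modality = modality,
                     index = seq_len(nrow(w)), weight = w[, f])
    }))
  }
  dplyr::bind_rows(
    one(x$W1, "frequency"), one(x$W2, "temporal"),
    one(x$W3, "spatial"), one(x$Q, "response")
  )
}

#' @rdname tidy.npls_model
#' @method glance npls_model
#' @export
glance.npls_model <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    n_features = prod(x$dims),
    n_response = x$n_response,
    final_rss = if (length(x$rss)) x$rss[length(x$rss)] else NA_real_,
    truncated = isTRUE(x$truncated)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
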