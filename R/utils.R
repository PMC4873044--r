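# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All exported generators route their randomness through this, which is
# what makes them pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Unfold an N x I1 x I2 x I3 array into the N x (I1*I2*I3) matrix whose column
# index runs fastest over mode 1 (column-major vec of each observation's cube).
unfold_obs <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  matrix(as.vector(x), nrow = d[1L])
}

# Inverse of unfold_obs given the three feature-mode dimensions.
fold_obs <- function(xm, dims3) {
  array(as.vector(xm), dim = c(nrow(xm), dims3))
}

# vec of a rank-one cube w1 o w2 o w3, in the same ordering as unfold_obs.
vec_rank1 <- function(w1, w2, w3) {
  as.vector(outer(outer(w1, w2), w3))
}

# Flip a vector so that its first entry of non-negligible magnitude is
# positive; returns +1/-1 so callers can compensate elsewhere.
sign_flip <- function(w, tol = 1e-12) {
  idx <- which(abs(w) > tol)
  if (length(idx) == 0L) return(1)
  if (w[idx[1L]] < 0) -1 else 1
}

l2 <- function(x) sqrt(sum(x^2))

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  invisible(x)
}

# Coerce a trajectory given either as a tibble/data.frame with a time column
# and coordinate columns, or as a plain numeric matrix, to a numeric matrix.
traj_matrix <- function(y) {
  if (is.data.frame(y)) {
    nm <- names(y)
    keep <- setdiff(nm, "time")
    as.matrix(y[keep])
  } else {
    as.matrix(y)
  }
}

traj_times <- function(y) {
  if (is.data.frame(y) && "time" %in% names(y)) {
    y$time
  } else {
    attr(y, "times")
  }
}
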