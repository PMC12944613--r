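# Internal numeric helpers shared across modules.

# Evaluate expr with a local RNG stream from an explicit seed; the caller's
# global .Random.seed is untouched.
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

rowNorms <- function(m) sqrt(rowSums(m * m))

normalizeRows <- function(m) {
  n <- rowNorms(m)
  n[n == 0] <- 1
  m / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product of n x 3 matrices
crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Rodrigues: axis-angle vector -> rotation matrix
rotvecToMatrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) {
    K <- matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
    return(diag(3) + K)
  }
  k <- r / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotation matrix -> axis-angle vector
matrixToRotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near pi: extract axis from R + I
    A <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(A), 0))
    i <- which.max(ax)
    ax <- A[, i] / ax[i]
    ax <- ax / sqrt(sum(ax^2))
    return(ax * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

# nearest rotation matrix (special orthogonal projection)
projectSO3 <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

# unit quaternion (w, x, y, z) <-> rotation matrix, for trajectory I/O
matrixToQuat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quatToMatrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# angular difference between two rotations, degrees
rotationAngleDeg <- function(R1, R2 = diag(3)) {
  ct <- (sum(diag(t(R2) %*% R1)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

stopifnot3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3 || anyNA(x))
    stop(sprintf("'%s' must be a numeric length-3 vector", what), call. = FALSE)
  as.numeric(x)
}
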