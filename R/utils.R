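# Small geometry helpers shared across the package. All vectors are rows of
# n x 3 matrices in the global frame unless stated otherwise.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise cross product of two n x 3 matrices (or a matrix and one vector)
#' @noRd
cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = max(1, NROW(b)), ncol = 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, nrow = nrow(a), ncol = 3, byrow = TRUE)
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

row_norms <- function(m) sqrt(rowSums(m^2))

#' Convert unit quaternions (n x 4, order w,x,y,z) to rotation matrices.
#' Returns a list of 3x3 matrices, or a single matrix if n == 1.
#' @noRd
quat_to_matrix <- function(q) {
  one <- is.null(dim(q))
  if (one) q <- matrix(q, nrow = 1)
  out <- lapply(seq_len(nrow(q)), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), nrow = 3, byrow = TRUE)
  })
  if (one) out[[1]] else out
}

#' Quaternion (w,x,y,z) for a rotation of `angle` radians about unit `axis`.
#' @noRd
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotate the rows of an n x 3 matrix by a single 3 x 3 rotation matrix.
#' @noRd
rotate_rows <- function(m, R) m %*% t(R)

#' Apply per-sample rotations (list of 3x3) to the constant local vector v.
#' @noRd
rotate_local_vector <- function(Rs, v) {
  t(vapply(Rs, function(R) as.numeric(R %*% v), numeric(3)))
}

is_uniform_grid <- function(time, tol = 1e-9) {
  if (length(time) < 2L) return(TRUE)
  dt <- diff(time)
  max(abs(dt - dt[1])) < tol * max(1, abs(dt[1]))
}

#' Central finite differences column-wise on a uniform grid; one-sided at the
#' endpoints. Exact for signals linear in time.
#' @noRd
central_diff <- function(x, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("central_diff: need at least 3 samples", call. = FALSE)
  d <- x
  d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
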