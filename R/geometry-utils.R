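# Small rigid-body geometry helpers shared by the kinematics and muscle-path
# code. All transforms are 4x4 homogeneous matrices; rotations 3x3.

#' Elementary rotation matrices
#'
#' Right-handed rotations about the x, y or z axis.
#'
#' @param theta angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
#' @name rotations
NULL

#' @rdname rotations
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname rotations
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' @rdname rotations
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#' @param axis length-3 axis (normalized internally).
#' @param theta angle in radians.
#' @keywords internal
rot_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- skew3(u)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Inverse of skew3: extract the axial vector of a (near) skew matrix
#' @keywords internal
vee3 <- function(S) {
  c(S[3, 2] - S[2, 3], S[1, 3] - S[3, 1], S[2, 1] - S[1, 2]) / 2
}

#' Build a homogeneous transform
#' @param R 3x3 rotation. @param p length-3 translation.
#' @keywords internal
make_transform <- function(R = diag(3), p = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- p
  T
}

#' @keywords internal
transform_inverse <- function(T) {
  R <- t(T[1:3, 1:3])
  make_transform(R, -R %*% T[1:3, 4])
}

#' Apply a homogeneous transform to one point (length-3)
#' @keywords internal
transform_point <- function(T, p) {
  drop(T[1:3, 1:3] %*% p) + T[1:3, 4]
}

#' Apply a homogeneous transform to an n x 3 matrix of points
#' @keywords internal
transform_points <- function(T, P) {
  P <- matrix(P, ncol = 3)
  sweep(P %*% t(T[1:3, 1:3]), 2, T[1:3, 4], "+")
}

#' Unit vector
#' @keywords internal
normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Closest point on an ellipsoid (axis-aligned, centered) to a point
#'
#' Solves the orthogonal-projection problem p_i = x_i * r_i^2 / (r_i^2 + t)
#' with the Lagrange multiplier t found by safeguarded Newton on
#' f(t) = sum((x_i r_i / (r_i^2 + t))^2) - 1 = 0. Works for points inside or
#' outside the surface.
#'
#' @param x length-3 point in the ellipsoid frame.
#' @param radii length-3 positive semi-axes.
#' @return length-3 closest point on the surface.
#' @keywords internal
project_point_ellipsoid <- function(x, radii) {
  r2 <- radii^2
  if (all(abs(x) < 1e-300)) return(c(0, 0, min(radii)) * c(0, 0, 1))
  f <- function(t) sum((x * radii / (r2 + t))^2) - 1
  # t ranges over (-min(r2), Inf); f is decreasing there.
  lo <- -min(r2) + 1e-14 * min(r2)
  t <- 0
  if (f(t) < 0) { # x inside: t < 0
    hi <- 0
    # lo end -> f -> +Inf
    for (i in 1:200) {
      t <- (lo + hi) / 2
      if (f(t) > 0) lo <- t else hi <- t
      if (hi - lo < 1e-15 * max(1, abs(t))) break
    }
  } else {
    hi <- max(r2) * 2 + sum(abs(x) * radii)
    while (f(hi) > 0) hi <- hi * 2
    lo2 <- 0
    for (i in 1:200) {
      t <- (lo2 + hi) / 2
      if (f(t) > 0) lo2 <- t else hi <- t
      if (hi - lo2 < 1e-15 * max(1, abs(t))) break
    }
  }
  x * r2 / (r2 + t)
}

#' Trapezoidal integral
#' @keywords internal
trapz_int <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}
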