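#' Rigid transforms in SE(3)
#'
#' A `rigid_transform` is a rotation matrix `R` (3x3, dimensionless) together
#' with a translation vector `t` (length 3, millimetres), acting on column
#' points as `p' = R p + t`. All registration stages estimate or compose
#' objects of this class. Rotations must be proper (det = +1) and orthonormal
#' to within `1e-9`; inputs failing the check are rejected rather than
#' silently re-orthonormalised (see [orthonormalize_rotation()] for the
#' explicit utility).
#'
#' @param R 3x3 rotation matrix.
#' @param t numeric translation vector of length 3 (mm).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' X <- rigid_transform(rotation_about_z(pi / 4), c(10, -5, 2))
#' compose(invert(X), X) # identity
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  if (!all(dim(R) == c(3L, 3L)) || length(t) != 3L) {
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation",
         call. = FALSE)
  }
  if (!all(is.finite(R)) || !all(is.finite(t))) {
    stop("invalid transform: non-finite entries", call. = FALSE)
  }
  check_rotation(R)
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  angle:", format(rotation_angle(x$R) * 180 / pi, digits = 6),
      "deg  |t|:", format(sqrt(sum(x$t^2)), digits = 6), "mm\n")
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(NULL, c("R1", "R2", "R3", "t"))
  print(round(m, 6))
  invisible(x)
}

# Reject non-rotations: orthonormality and det(+1) within 1e-9.
check_rotation <- function(R, tol = 1e-9) {
  err <- norm(crossprod(R) - diag(3), "F")
  d <- det(R)
  if (err > tol || abs(d - 1) > tol) {
    stop(sprintf(
      "invalid transform: rotation fails SO(3) check (orthonormality error %.3g, det %.12f)",
      err, d), call. = FALSE)
  }
  invisible(TRUE)
}

#' Identity rigid transform
#' @return The identity `rigid_transform`.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' Returns the transform mapping `p` to `A.R (B.R p + B.t) + A.t`, i.e. `B`
#' applied first, then `A` (the usual matrix-product order `A %*% B` of their
#' homogeneous forms).
#'
#' @param A,B `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose <- function(A, B) {
  stopifnot(inherits(A, "rigid_transform"), inherits(B, "rigid_transform"))
  rigid_transform(A$R %*% B$R, as.numeric(A$R %*% B$t) + A$t)
}

#' Invert a rigid transform
#'
#' @param A a `rigid_transform`.
#' @return The inverse transform `(R^T, -R^T t)`.
#' @export
invert <- function(A) {
  stopifnot(inherits(A, "rigid_transform"))
  Rt <- t(A$R)
  rigid_transform(Rt, -as.numeric(Rt %*% A$t))
}

#' Apply a rigid transform to a point cloud or coordinate matrix
#'
#' Points map as `R p + t`; normals, being translation-invariant directions,
#' map by the rotation only.
#'
#' @param A a `rigid_transform`.
#' @param cloud a [point_cloud()] or an N x 3 coordinate matrix.
#' @return An object of the same kind as `cloud`, transformed.
#' @export
apply_transform <- function(A, cloud) {
  stopifnot(inherits(A, "rigid_transform"))
  if (is.matrix(cloud) || is.numeric(cloud)) {
    pts <- as_points_matrix(cloud)
    return(transform_points(A, pts))
  }
  stopifnot(inherits(cloud, "point_cloud"))
  out <- point_cloud(
    transform_points(A, cloud$points),
    normals = if (is.null(cloud$normals)) NULL else cloud$normals %*% t(A$R)
  )
  out
}

#' Apply a rigid transform to a coordinate matrix
#'
#' Maps each row `p` of `pts` to `R p + t`. For [point_cloud()] objects use
#' [apply_transform()], which also rotates stored normals.
#'
#' @param A a [rigid_transform()].
#' @param pts N x 3 coordinate matrix (mm).
#' @return The transformed N x 3 matrix.
#' @export
transform_points <- function(A, pts) {
  sweep(pts %*% t(A$R), 2L, A$t, "+")
}

#' Exponential map of so(3)
#'
#' Rodrigues' formula for the rotation `exp([w]x)` generated by a rotation
#' vector `w` (radians). Numerically stable near `|w| = 0` via the series
#' expansion of the coefficient terms.
#'
#' @param omega rotation vector, length 3 (radians).
#' @return A 3x3 rotation matrix.
#' @export
exp_so3 <- function(omega) {
  omega <- as.numeric(omega)
  stopifnot(length(omega) == 3L, all(is.finite(omega)))
  th <- sqrt(sum(omega^2))
  K <- skew3(omega)
  if (th < 1e-8) {
    # second-order series: I + K + K^2/2 is accurate to O(th^3)
    R <- diag(3) + K + 0.5 * (K %*% K)
  } else {
    R <- diag(3) + (sin(th) / th) * K + ((1 - cos(th)) / th^2) * (K %*% K)
  }
  # clean up round-off so downstream SO(3) checks at 1e-9 always pass
  orthonormalize_rotation(R)
}

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

#' Rotation angle of a rotation matrix
#'
#' `acos((trace(R) - 1) / 2)` clamped to `[0, pi]`, the geodesic angle of the
#' rotation. Used to evaluate the angular stopping rule of the iterative
#' refinement.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  check_rotation(as.matrix(R), tol = 1e-7)
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
}

#' Project a near-rotation onto SO(3)
#'
#' Explicit re-orthonormalisation utility via SVD (nearest rotation in
#' Frobenius norm, with the reflection guard). Validity checks elsewhere never
#' call this silently.
#'
#' @param R approximate 3x3 rotation.
#' @return The closest proper rotation matrix.
#' @export
orthonormalize_rotation <- function(R) {
  s <- svd(R)
  D <- diag(c(1, 1, det(s$u %*% t(s$v))))
  s$u %*% D %*% t(s$v)
}

#' Elementary rotations about coordinate axes
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_z <- function(theta) {
  exp_so3(c(0, 0, theta))
}

#' @rdname rotation_about_z
#' @export
rotation_about_x <- function(theta) exp_so3(c(theta, 0, 0))

#' @rdname rotation_about_z
#' @export
rotation_about_y <- function(theta) exp_so3(c(0, theta, 0))

#' Rotation about an arbitrary unit axis
#' @param axis direction (normalised internally).
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero", call. = FALSE)
  exp_so3(axis / n * theta)
}

#' Homogeneous 4x4 view of a rigid transform
#'
#' Serialization view only; the package's point convention is `p' = R p + t`.
#'
#' @param A a `rigid_transform`.
#' @return A 4x4 numeric matrix.
#' @export
as_homogeneous <- function(A) {
  stopifnot(inherits(A, "rigid_transform"))
  rbind(cbind(A$R, A$t), c(0, 0, 0, 1))
}

#' @rdname as_homogeneous
#' @param M a 4x4 homogeneous matrix.
#' @export
from_homogeneous <- function(M) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(4L, 4L)))
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}
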