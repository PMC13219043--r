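#' Paired-landmark rigid alignment (three-point / Kabsch method)
#'
#' Closed-form least-squares rigid alignment of `N >= 3` paired landmarks:
#' both sets are centred on their centroids, the cross-covariance
#' `H = sum (p_i - cs)(q_i - ct)^T` is decomposed by SVD `H = U S V^T`, and
#' the rotation is `R = V D U^T` with `D = diag(1, 1, det(V U^T))`. The
#' determinant guard keeps `R` a proper rotation even when noisy or coplanar
#' landmarks would make the unguarded `V U^T` a reflection; it coincides with
#' the plain product whenever `det(V U^T) = +1`. The translation is
#' `t = -R cs + ct`. In navigation use the source frame is the tracker
#' (patient) space and the target frame the CT space.
#'
#' @param source N x 3 matrix of landmark coordinates in the source frame (mm).
#' @param target N x 3 matrix of the paired coordinates in the target frame.
#' @return A `coarse_solution` list: `transform` (the fitted
#'   [rigid_transform()]), `H` (cross-covariance, mm^2), `centroid_source`,
#'   `centroid_target`, `rms_residual` (mm), `singular_values` of `H`, and a
#'   logical `collinear` diagnostic flag (always `FALSE` on success).
#' @examples
#' src <- matrix(c(0, 0, 0, 30, 0, 0, 0, 25, 0), ncol = 3, byrow = TRUE)
#' X <- rigid_transform(rotation_about_z(0.4), c(10, -5, 2))
#' fit <- kabsch_align(src, apply_transform(X, src))
#' fit$rms_residual # ~0
#' @export
kabsch_align <- function(source, target) {
  src <- as_points_matrix(source)
  tgt <- as_points_matrix(target)
  if (nrow(src) != nrow(tgt)) {
    stop("kabsch_align: source and target must pair up row by row", call. = FALSE)
  }
  n <- nrow(src)
  if (n < 3L) {
    stop(sprintf("insufficient landmarks: need at least 3 pairs, got %d", n),
         call. = FALSE)
  }
  if (!all(is.finite(src)) || !all(is.finite(tgt))) {
    stop("kabsch_align: non-finite landmark coordinates", call. = FALSE)
  }
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  Ps <- sweep(src, 2L, cs)
  Pt <- sweep(tgt, 2L, ct)
  H <- t(Ps) %*% Pt
  sv <- svd(H)
  # degenerate geometry: collinear (or coincident) source points leave the
  # rotation about the line unconstrained
  if (sv$d[1] <= 0 || sv$d[2] < 1e-9 * sv$d[1]) {
    stop(sprintf(
      "degenerate landmark geometry: collinear or coincident points (singular values %.3g, %.3g, %.3g mm^2)",
      sv$d[1], sv$d[2], sv$d[3]), call. = FALSE)
  }
  d <- det(sv$v %*% t(sv$u))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transform <- rigid_transform(orthonormalize_rotation(R),
                               as.numeric(-R %*% cs + ct))
  structure(list(
    transform = transform,
    H = H,
    centroid_source = cs,
    centroid_target = ct,
    rms_residual = landmark_fre(src, tgt, transform),
    singular_values = sv$d,
    collinear = FALSE
  ), class = "coarse_solution")
}

#' @export
print.coarse_solution <- function(x, ...) {
  cat(sprintf("<coarse_solution>  rms residual %.4f mm  (singular values %s mm^2)\n",
              x$rms_residual, paste(signif(x$singular_values, 4), collapse = ", ")))
  print(x$transform)
  invisible(x)
}

#' Root-mean-square landmark registration residual
#'
#' The fiducial registration error of a candidate transform over paired
#' landmarks: `sqrt(mean ||R p_i + t - q_i||^2)`.
#'
#' @param source,target paired N x 3 landmark matrices (mm).
#' @param transform a [rigid_transform()].
#' @return RMS residual in mm.
#' @export
landmark_fre <- function(source, target, transform) {
  src <- as_points_matrix(source)
  tgt <- as_points_matrix(target)
  stopifnot(nrow(src) == nrow(tgt))
  mapped <- transform_points(transform, src)
  sqrt(mean(rowSums((mapped - tgt)^2)))
}
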