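#' Point clouds in millimetres
#'
#' An N x 3 coordinate matrix with optional unit surface normals. Both the
#' sparse probe-acquired source set (a few dozen points) and the dense
#' CT-derived target surface (tens of thousands of points) are represented
#' this way.
#'
#' @param points N x 3 numeric matrix of coordinates (mm).
#' @param normals optional N x 3 matrix of unit direction vectors. Rows must
#'   have Euclidean norm 1 within `1e-6`.
#' @return An object of class `point_cloud` with elements `points` and
#'   (possibly `NULL`) `normals`.
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as_points_matrix(points)
  if (!all(is.finite(points))) {
    stop("point_cloud: non-finite coordinates", call. = FALSE)
  }
  if (!is.null(normals)) {
    normals <- as_points_matrix(normals)
    if (nrow(normals) != nrow(points)) {
      stop("point_cloud: normals count must equal point count", call. = FALSE)
    }
    nn <- sqrt(rowSums(normals^2))
    if (any(!is.finite(nn)) || any(abs(nn - 1) > 1e-6)) {
      stop("point_cloud: normals must be unit length within 1e-6", call. = FALSE)
    }
  }
  structure(list(points = points, normals = normals), class = "point_cloud")
}

as_points_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop("coordinates must come in triples", call. = FALSE)
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinate matrix must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points (mm)%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else ", with unit normals"))
  if (nrow(x$points) > 0) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  bbox: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return Integer count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' Subset a point cloud by row index
#' @param cloud a `point_cloud`.
#' @param idx integer or logical index.
#' @return A `point_cloud` carrying normals along when present.
#' @export
subset_cloud <- function(cloud, idx) {
  stopifnot(inherits(cloud, "point_cloud"))
  point_cloud(cloud$points[idx, , drop = FALSE],
              normals = if (is.null(cloud$normals)) NULL
                        else cloud$normals[idx, , drop = FALSE])
}
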