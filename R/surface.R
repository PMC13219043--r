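#' Estimate surface normals by local PCA plane fitting
#'
#' For every point the `k_neighbors` nearest points (the query point included)
#' define a neighbourhood; the unit eigenvector belonging to the smallest
#' eigenvalue of the neighbourhood covariance is the local normal. This is the
#' least-squares local plane fit: it minimises the sum of squared
#' perpendicular distances of the neighbours to the plane. Signs are left
#' unoriented because every registration residual enters as `|n . r|` (even in
#' the sign of `n`); see [orient_normals_outward()] for a visualization aid.
#'
#' @param cloud a [point_cloud()].
#' @param k_neighbors neighbourhood size including the query point
#'   (default 30).
#' @return The cloud with `normals` filled in.
#' @export
estimate_normals <- function(cloud, k_neighbors = 30L) {
  stopifnot(inherits(cloud, "point_cloud"))
  k <- as.integer(k_neighbors)
  if (k < 3L) stop("k_neighbors must be at least 3", call. = FALSE)
  if (n_points(cloud) < k) {
    stop("cloud has fewer points than k_neighbors", call. = FALSE)
  }
  nrm <- .pca_normals(cloud$points, k)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  point_cloud(cloud$points, normals = nrm)
}

#' Flip normals to point away from a reference point (diagnostic only)
#'
#' @param cloud a `point_cloud` with normals.
#' @param center reference point; defaults to the cloud centroid.
#' @return The cloud with consistently outward normals.
#' @export
orient_normals_outward <- function(cloud, center = colMeans(cloud$points)) {
  stopifnot(inherits(cloud, "point_cloud"), !is.null(cloud$normals))
  out <- sweep(cloud$points, 2L, as.numeric(center))
  flip <- rowSums(out * cloud$normals) < 0
  nrm <- cloud$normals
  nrm[flip, ] <- -nrm[flip, ]
  point_cloud(cloud$points, normals = nrm)
}

#' Build an exact kd-tree spatial index over a point cloud
#'
#' Nearest-neighbour queries against the index are exact; ties in distance
#' resolve deterministically to the lowest point index.
#'
#' @param cloud a [point_cloud()] (the dense registration target, usually with
#'   normals already estimated).
#' @return A `spatial_index` object used by [find_correspondences()] and
#'   [query_index()].
#' @export
build_spatial_index <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop("cannot index an empty cloud", call. = FALSE)
  structure(list(ptr = .kdtree_build(cloud$points), cloud = cloud),
            class = "spatial_index")
}

#' @export
print.spatial_index <- function(x, ...) {
  cat(sprintf("<spatial_index> kd-tree over %d points%s\n", n_points(x$cloud),
              if (is.null(x$cloud$normals)) "" else " (with normals)"))
  invisible(x)
}

#' k-nearest-neighbour query against a spatial index
#'
#' @param index a `spatial_index`.
#' @param queries M x 3 matrix (or `point_cloud`) of query coordinates.
#' @param k number of neighbours.
#' @return A list with integer matrix `idx` (M x k, 1-based indices into the
#'   indexed cloud) and numeric matrix `dist` (mm), nearest first.
#' @export
query_index <- function(index, queries, k = 1L) {
  stopifnot(inherits(index, "spatial_index"))
  q <- if (inherits(queries, "point_cloud")) queries$points else as_points_matrix(queries)
  .kdtree_query(index$ptr, q, as.integer(k))
}

#' Gated nearest-neighbour correspondences
#'
#' Each source point is matched to its exact nearest neighbour in the indexed
#' target cloud; pairs farther apart than `d_max` are gated out (their `kept`
#' mask entry is `FALSE`). The matched target normals ride along for the
#' point-to-plane residuals.
#'
#' @param source a [point_cloud()] of probe points, already expressed in the
#'   target frame under the current pose estimate.
#' @param index a `spatial_index` built over a target cloud carrying normals.
#' @param d_max correspondence distance gate in mm (default 5.0).
#' @return A `correspondence_set`: `source`, `target`, `normal` (N x 3
#'   matrices), `dist` (mm), `kept` (logical), `source_index`, `target_index`.
#' @export
find_correspondences <- function(source, index, d_max = 5.0) {
  stopifnot(inherits(source, "point_cloud"), inherits(index, "spatial_index"))
  if (is.null(index$cloud$normals)) {
    stop("target cloud lacks normals: run estimate_normals() before building the index",
         call. = FALSE)
  }
  stopifnot(is.finite(d_max), d_max > 0)
  res <- query_index(index, source, k = 1L)
  ti <- as.integer(res$idx[, 1L])
  d <- as.numeric(res$dist[, 1L])
  structure(list(
    source = source$points,
    target = index$cloud$points[ti, , drop = FALSE],
    normal = index$cloud$normals[ti, , drop = FALSE],
    dist = d,
    kept = d <= d_max,
    source_index = seq_len(n_points(source)),
    target_index = ti,
    d_max = d_max
  ), class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("<correspondence_set> %d/%d kept (gate %.2f mm, max dist %.3f mm)\n",
              sum(x$kept), length(x$kept), x$d_max, max(x$dist)))
  invisible(x)
}

# Restrict a correspondence set to its kept pairs.
kept_pairs <- function(corrs) {
  stopifnot(inherits(corrs, "correspondence_set"))
  k <- corrs$kept
  list(
    source = corrs$source[k, , drop = FALSE],
    target = corrs$target[k, , drop = FALSE],
    normal = corrs$normal[k, , drop = FALSE],
    source_index = corrs$source_index[k],
    target_index = corrs$target_index[k]
  )
}

#' Crop a point cloud to a spherical region of interest
#'
#' Keeps the points within `radius` of `center`; normals are carried along.
#' Registration restricts the dense CT cloud to the surgically exposed patch
#' this way before correspondence search.
#'
#' @param cloud a [point_cloud()].
#' @param center ROI centre, length-3 (mm).
#' @param radius ROI radius in mm (> 0).
#' @return The cropped `point_cloud`; an empty result triggers a warning, not
#'   an error, so the caller can decide.
#' @export
crop_roi <- function(cloud, center, radius) {
  stopifnot(inherits(cloud, "point_cloud"), radius > 0)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  d2 <- rowSums(sweep(cloud$points, 2L, center)^2)
  idx <- d2 <= radius^2
  if (!any(idx)) {
    warning("crop_roi: no points inside the region of interest")
    return(point_cloud(matrix(numeric(0), 0, 3),
                       normals = if (is.null(cloud$normals)) NULL
                                 else matrix(numeric(0), 0, 3)))
  }
  subset_cloud(cloud, idx)
}

#' Default spherical ROI around the coarse-aligned source
#'
#' The region of interest is a sphere centred at the coarse-transformed source
#' centroid with radius `margin` times the source bounding-sphere radius: the
#' whole probed patch plus a safety margin.
#'
#' @param source sparse source `point_cloud` (probe frame).
#' @param coarse a [rigid_transform()] mapping source to target frame.
#' @param margin radius multiplier (default 1.5).
#' @return List with `center` and `radius` (mm).
#' @export
default_roi <- function(source, coarse, margin = 1.5) {
  stopifnot(inherits(source, "point_cloud"))
  mapped <- transform_points(coarse, source$points)
  ctr <- colMeans(mapped)
  r <- sqrt(max(rowSums(sweep(mapped, 2L, ctr)^2)))
  list(center = ctr, radius = margin * r)
}
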