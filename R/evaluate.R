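#' Target registration error
#'
#' Mean Euclidean distance between the true fiducial positions and the
#' positions predicted by the registration:
#' `TRE = (1/m) * sum_j ||true_j - est_j||`.
#'
#' @param fiducials_true m x 3 matrix of reference positions (mm).
#' @param fiducials_est m x 3 matrix of registered positions (mm).
#' @return TRE in mm.
#' @export
compute_tre <- function(fiducials_true, fiducials_est) {
  a <- as_points_matrix(fiducials_true)
  b <- as_points_matrix(fiducials_est)
  if (nrow(a) == 0L) stop("compute_tre: need at least one fiducial", call. = FALSE)
  if (nrow(a) != nrow(b)) stop("compute_tre: fiducial sets must pair up", call. = FALSE)
  mean(sqrt(rowSums((a - b)^2)))
}

#' Surface residual metrics: RMSE, population STD, maximum error
#'
#' From per-pair residual distances `e_i`:
#' `RMSE = sqrt(mean(e_i^2))`, `STD = sqrt(mean((e_i - mean(e))^2))`
#' (population divisor `n`), `MaxErr = max(e_i)`.
#'
#' @param errors non-negative per-pair distances (mm).
#' @return List with `rmse`, `std`, `max_err` (mm).
#' @export
compute_surface_metrics <- function(errors) {
  e <- as.numeric(errors)
  if (length(e) == 0L) stop("compute_surface_metrics: empty input", call. = FALSE)
  if (any(!is.finite(e)) || any(e < 0)) {
    stop("compute_surface_metrics: distances must be finite and >= 0", call. = FALSE)
  }
  list(rmse = sqrt(mean(e^2)),
       std = sqrt(mean((e - mean(e))^2)),
       max_err = max(e))
}

# Exact distance from points to a triangle mesh. Candidate faces come from a
# kd-tree over face centroids (top n_cand); the closest point on each
# candidate is the interior plane projection when its barycentric
# coordinates are inside, else the nearest point on an edge.
point_mesh_distance <- function(points, mesh, n_cand = 60L) {
  P <- as_points_matrix(points)
  V <- mesh$vertices
  F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  ctr <- (A + B + C) / 3
  # any point of a face lies within r_max of its centroid, so a face whose
  # centroid is farther than d_best + r_max cannot contain a closer point:
  # checking that bound against the last candidate makes the result exact
  r_max <- sqrt(max(rowSums((A - ctr)^2), rowSums((B - ctr)^2),
                    rowSums((C - ctr)^2)))
  tree <- .kdtree_build(ctr)
  n_cand <- min(n_cand, nrow(F))
  q <- .kdtree_query(tree, P, n_cand)
  out <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    fi <- q$idx[i, ]
    d_best <- sqrt(min(point_triangles_d2(P[i, ], A[fi, , drop = FALSE],
                                          B[fi, , drop = FALSE],
                                          C[fi, , drop = FALSE])))
    if (n_cand < nrow(F) && d_best > q$dist[i, n_cand] - r_max) {
      keep <- rowSums(sweep(ctr, 2L, P[i, ])^2) <= (d_best + r_max)^2
      d_best <- sqrt(min(point_triangles_d2(P[i, ], A[keep, , drop = FALSE],
                                            B[keep, , drop = FALSE],
                                            C[keep, , drop = FALSE])))
    }
    out[i] <- d_best
  }
  out
}

# squared distances from one point to many triangles (a, b, c: k x 3)
point_triangles_d2 <- function(p, a, b, cc) {
  e1 <- b - a
  e2 <- cc - a
  w <- sweep(-a, 2L, p, "+") # p - a
  d11 <- rowSums(e1 * e1)
  d12 <- rowSums(e1 * e2)
  d22 <- rowSums(e2 * e2)
  w1 <- rowSums(w * e1)
  w2 <- rowSums(w * e2)
  det <- pmax(d11 * d22 - d12^2, .Machine$double.xmin)
  u <- (d22 * w1 - d12 * w2) / det
  v <- (d11 * w2 - d12 * w1) / det
  inside <- u >= 0 & v >= 0 & u + v <= 1
  proj <- a + u * e1 + v * e2
  d2 <- rowSums((sweep(proj, 2L, p, "-"))^2)
  if (any(!inside)) {
    seg <- pmin(point_segments_d2(p, a, b),
                point_segments_d2(p, a, cc),
                point_segments_d2(p, b, cc))
    d2[!inside] <- seg[!inside]
  }
  d2
}

point_segments_d2 <- function(p, a, b) {
  ab <- b - a
  t <- rowSums(sweep(-a, 2L, p, "+") * ab) / pmax(rowSums(ab * ab), .Machine$double.xmin)
  t <- pmin(pmax(t, 0), 1)
  q <- a + t * ab
  rowSums((sweep(q, 2L, p, "-"))^2)
}

#' Evaluate a registration against the phantom ground truth
#'
#' TRE comes from the fiducials: the patient-frame fiducials are mapped by
#' the candidate total transform and compared with their true CT-frame
#' positions. Surface metrics (RMSE/STD/MaxErr) come from the mapped probe
#' points under two pairings: `nearest` — exact distance to the reconstructed
#' surface, mirroring intraoperative probe-on-bone verification (the
#' default-reported set) — and `truth`, distances to the known noise-free
#' foot points of each probe sample.
#'
#' @param phantom a [make_phantom()] result.
#' @param total_transform candidate patient-to-CT [rigid_transform()].
#' @return A `metrics_report`: `tre`, `rmse`, `std`, `max_err` (the nearest
#'   pairing), `m_fiducials`, `n_pairs`, plus `nearest` and `truth` sublists.
#' @export
evaluate_registration <- function(phantom, total_transform) {
  stopifnot(inherits(phantom, "synthetic_phantom"),
            inherits(total_transform, "rigid_transform"))
  fid_est <- transform_points(total_transform, phantom$fiducials_patient)
  tre <- compute_tre(phantom$fiducials_ct, fid_est)
  mapped <- transform_points(total_transform, phantom$probe_points$points)
  e_near <- point_mesh_distance(mapped, phantom$mesh)
  e_truth <- sqrt(rowSums((mapped - phantom$foot_points)^2))
  near <- compute_surface_metrics(e_near)
  truth <- compute_surface_metrics(e_truth)
  structure(c(list(tre = tre), near,
              list(m_fiducials = nrow(phantom$fiducials_ct),
                   n_pairs = length(e_near),
                   nearest = near, truth = truth)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TRE %.4f mm | RMSE %.4f | STD %.4f | MaxErr %.4f (over %d fiducials, %d pairs)\n",
              x$tre, x$rmse, x$std, x$max_err, x$m_fiducials, x$n_pairs))
  invisible(x)
}
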