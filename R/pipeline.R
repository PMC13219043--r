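#' Full two-stage registration pipeline
#'
#' Convenience wrapper running the complete patient-registration workflow:
#' coarse alignment from paired landmarks, spherical ROI restriction of the
#' dense target around the coarse-aligned probe cloud, PCA normal estimation
#' on the restricted target, then the selected fine refinement initialised at
#' the coarse pose. Returns every stage separately as well as the total
#' transform.
#'
#' @param source sparse probe [point_cloud()] (patient/tracker frame).
#' @param target dense CT-frame [point_cloud()] or [tri_mesh()] (vertices are
#'   used).
#' @param landmarks paired landmark list (`$source`, `$target`), e.g. from
#'   [read_landmarks()] or a phantom's `coarse_landmarks`.
#' @param method `"sparse_p2pl"` (default), `"p2pl"`, `"p2pt"`, or
#'   `"coarse_only"`.
#' @param params a [sparse_icp_params()].
#' @param k_neighbors normal-estimation neighbourhood (default 30).
#' @param roi_margin ROI radius multiplier (see [default_roi()]); `NULL`
#'   disables cropping.
#' @param log_file optional JSON-lines log sink.
#' @return List with `coarse` (the `coarse_solution`), `fine`
#'   ([rigid_transform()] of the refinement alone), `total` (fine composed
#'   onto coarse), `result` (the `icp_result`, `NULL` for `coarse_only`),
#'   and `n_target` (target points used after ROI restriction).
#' @export
register_pipeline <- function(source, target, landmarks,
                              method = c("sparse_p2pl", "p2pl", "p2pt",
                                         "coarse_only"),
                              params = sparse_icp_params(), k_neighbors = 30L,
                              roi_margin = 1.5, log_file = NULL) {
  method <- match.arg(method)
  if (inherits(target, "tri_mesh")) target <- point_cloud(target$vertices)
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  coarse <- kabsch_align(landmarks$source, landmarks$target)
  nav_log("info", sprintf("coarse alignment: rms residual %.4f mm",
                          coarse$rms_residual),
          log_file = log_file, log_level = "warn")
  if (!is.null(roi_margin)) {
    roi <- default_roi(source, coarse$transform, roi_margin)
    cropped <- crop_roi(target, roi$center, roi$radius)
    if (n_points(cropped) >= k_neighbors) target <- cropped
  }
  if (method == "coarse_only") {
    out <- list(coarse = coarse, fine = identity_transform(),
                total = coarse$transform, result = NULL,
                n_target = n_points(target))
    return(out)
  }
  if (is.null(target$normals)) target <- estimate_normals(target, k_neighbors)
  index <- build_spatial_index(target)
  result <- switch(method,
    sparse_p2pl = sparse_icp_register(source, index, coarse$transform, params),
    p2pl = icp_point_to_plane(source, index, coarse$transform, params),
    p2pt = icp_point_to_point(source, index, coarse$transform, params))
  nav_log("info",
          sprintf("fine registration (%s): %d iterations, stopped on %s",
                  method, nrow(result$trace), result$termination),
          data = list(trace = result$trace), log_file = log_file,
          log_level = "warn")
  list(coarse = coarse, fine = result$fine, total = result$transform,
       result = result, n_target = n_points(target))
}
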