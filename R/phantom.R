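#' Configuration of the synthetic bone phantom
#'
#' The phantom emulates the physical validation setup: a bone-like surface in
#' the CT frame, a ground-truth rigid transform between patient (tracker) and
#' CT frames, fiducial spheres mounted off the bone for target-registration
#' error evaluation, ~30 noisy probe points restricted to a surgically
#' accessible patch, cartilage-like one-sided outliers, and three noisy
#' coarse-registration landmarks.
#'
#' @param shape `"cup"` (acetabulum-like shell) or `"ball_shaft"` (femur-like
#'   head + shaft); see [make_bone_mesh()].
#' @param dense_n dense target-cloud size (default 50000).
#' @param n_probe probe sample count (default 30, the intraoperative
#'   operating point).
#' @param n_fiducials fiducial-sphere count (default 4, as on the fixture).
#' @param probe_noise_sigma isotropic probe noise SD in mm (default 0.2,
#'   representative of optical trackers).
#' @param outlier_fraction fraction of probe points displaced off the bone
#'   (default 0).
#' @param outlier_offset_range outlier stand-off interval in mm
#'   (default `c(2, 5)`).
#' @param landmark_noise_sigma patient-side landmark noise SD in mm
#'   (default 2.0).
#' @param gt_rotation_range per-axis ground-truth rotation range in degrees
#'   (default `c(-30, 30)`).
#' @param gt_translation_range per-axis ground-truth translation range in mm
#'   (default `c(-50, 50)`).
#' @param roi_cap_angle angular extent (degrees) of the probe-accessible
#'   spherical band (default 60).
#' @param seed integer seed; all phantom randomness derives from it.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(shape = c("cup", "ball_shaft"), dense_n = 50000L,
                           n_probe = 30L, n_fiducials = 4L,
                           probe_noise_sigma = 0.2, outlier_fraction = 0,
                           outlier_offset_range = c(2, 5),
                           landmark_noise_sigma = 2.0,
                           gt_rotation_range = c(-30, 30),
                           gt_translation_range = c(-50, 50),
                           roi_cap_angle = 60, seed = 1L) {
  shape <- match.arg(shape)
  cfg <- list(shape = shape, dense_n = as.integer(dense_n),
              n_probe = as.integer(n_probe),
              n_fiducials = as.integer(n_fiducials),
              probe_noise_sigma = probe_noise_sigma,
              outlier_fraction = outlier_fraction,
              outlier_offset_range = as.numeric(outlier_offset_range),
              landmark_noise_sigma = landmark_noise_sigma,
              gt_rotation_range = as.numeric(gt_rotation_range),
              gt_translation_range = as.numeric(gt_translation_range),
              roi_cap_angle = roi_cap_angle, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(cfg$dense_n >= 100L, "dense_n must be >= 100")
  chk(cfg$n_probe >= 3L, "n_probe must be >= 3 (minimum rigid constraint)")
  chk(cfg$n_fiducials >= 3L, "n_fiducials must be >= 3")
  chk(cfg$probe_noise_sigma >= 0, "probe_noise_sigma must be >= 0")
  chk(cfg$outlier_fraction >= 0 && cfg$outlier_fraction < 1,
      "outlier_fraction must be in [0, 1)")
  chk(length(cfg$outlier_offset_range) == 2L &&
        cfg$outlier_offset_range[1] <= cfg$outlier_offset_range[2] &&
        cfg$outlier_offset_range[1] >= 0,
      "outlier_offset_range must be a valid non-negative interval")
  chk(cfg$landmark_noise_sigma >= 0, "landmark_noise_sigma must be >= 0")
  chk(length(cfg$gt_rotation_range) == 2L &&
        cfg$gt_rotation_range[1] <= cfg$gt_rotation_range[2],
      "gt_rotation_range must be a valid interval (degrees)")
  chk(length(cfg$gt_translation_range) == 2L &&
        cfg$gt_translation_range[1] <= cfg$gt_translation_range[2],
      "gt_translation_range must be a valid interval (mm)")
  chk(cfg$roi_cap_angle > 0 && cfg$roi_cap_angle <= 90,
      "roi_cap_angle must be in (0, 90] degrees")
  chk(all(is.finite(unlist(cfg[vapply(cfg, is.numeric, logical(1))]))),
      "phantom config values must be finite")
  invisible(TRUE)
}

# Feature patches of the probe-accessible ROI: per shape, the face subsets a
# surgeon could reach, with the probing fractions and the void-side (probe
# approach) direction used for cartilage-like outlier displacement.
roi_features <- function(mesh, roi_cap_angle) {
  shape <- attr(mesh, "shape")
  sz <- attr(mesh, "size")
  V <- mesh$vertices
  F <- mesh$faces
  ctr <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
          V[F[, 3], , drop = FALSE]) / 3
  cap <- roi_cap_angle * pi / 180
  if (shape == "cup") {
    rr <- sqrt(rowSums(ctr^2))
    theta <- acos(pmin(1, pmax(-1, ctr[, 3] / rr)))
    list(
      inner = list(faces = which(mesh$regions == "inner" &
                                   theta <= pi / 2 + cap),
                   frac = 0.6,
                   void_dir = function(p) -p / sqrt(sum(p^2))),
      # probing follows the protocol: articular surface and around the rim;
      # the notch walls stay on the mesh but are not probed
      rim = list(faces = which(mesh$regions == "rim"), frac = 0.4,
                 void_dir = function(p) c(0, 0, 1))
    )
  } else {
    hc <- sz$head_center
    m <- sz$resection_normal
    d <- sweep(ctr, 2L, hc)
    ang_m <- acos(pmin(1, pmax(-1, (d %*% m) / sqrt(rowSums(d^2)))))
    list(
      head = list(faces = which(mesh$regions == "head" &
                                  ang_m <= sz$theta_cut + cap),
                  frac = 0.6,
                  void_dir = function(p) {
                    v <- p - hc
                    v / sqrt(sum(v^2))
                  }),
      resection = list(faces = which(mesh$regions == "resection"), frac = 0.25,
                       void_dir = function(p) m),
      shaft = list(faces = which(mesh$regions == "shaft" &
                                   ctr[, 3] > sz$shaft_length - 25),
                   frac = 0.15,
                   void_dir = function(p) {
                     v <- c(p[1], p[2], 0)
                     v / sqrt(sum(v^2))
                   })
    )
  }
}

# Three coarse-landmark sites, one per ROI feature, at azimuths chosen to
# maximise their spread: a tight landmark triangle would amplify the
# patient-side noise into large coarse rotation errors, which no fine stage
# could be expected to digest.
coarse_landmark_sites <- function(mesh) {
  shape <- attr(mesh, "shape")
  sz <- attr(mesh, "size")
  V <- mesh$vertices
  F <- mesh$faces
  ctr <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
          V[F[, 3], , drop = FALSE]) / 3
  nearest_site <- function(region, target) {
    idx <- which(mesh$regions == region)
    d2 <- rowSums(sweep(ctr[idx, , drop = FALSE], 2L, target)^2)
    ctr[idx[which.min(d2)], ]
  }
  if (shape == "cup") {
    r <- sz$outer_radius
    rbind(
      nearest_site("inner", r * c(sin(2.0) * cos(pi), sin(2.0) * sin(pi), cos(2.0))),
      nearest_site("rim", (r + 2) * c(cos(-pi / 2), sin(-pi / 2), 0)),
      nearest_site("notch_wall", (r - 7) *
                     c(cos(sz$notch_half_angle), sin(sz$notch_half_angle), 0))
    )
  } else {
    hc <- sz$head_center
    m <- sz$resection_normal
    u <- c(-m[1], -m[2], 0)
    u <- u / sqrt(sum(u^2))
    rbind(
      nearest_site("head", hc + sz$head_radius * u),
      nearest_site("resection", sz$resection_center),
      nearest_site("shaft", c(sz$shaft_radius * cos(3 * pi / 4),
                              sz$shaft_radius * sin(3 * pi / 4),
                              sz$shaft_length - 5))
    )
  }
}

# Stratified surface sampling over the ROI: probe counts are split across the
# feature patches by their fractions, and within a patch the faces are cut
# into equal-area azimuthal strata; one area-weighted sample is drawn per
# stratum, honouring the "evenly distributed around the rim" protocol.
sample_roi_points <- function(mesh, n, roi_cap_angle, seed) {
  feats <- roi_features(mesh, roi_cap_angle)
  fracs <- vapply(feats, function(f) f$frac, numeric(1))
  counts <- diff(c(0L, round(cumsum(fracs) * n)))
  counts <- pmax(counts, if (n >= length(feats)) 1L else 0L)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n) counts[which.max(fracs)] <- counts[which.max(fracs)] + 1L
  V <- mesh$vertices
  F <- mesh$faces
  areas <- triangle_areas(V, F)
  ctr <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
          V[F[, 3], , drop = FALSE]) / 3
  pts <- matrix(0, n, 3)
  faces <- integer(n)
  feat_of <- character(n)
  row <- 0L
  with_seed(seed, {
    for (nm in names(feats)) {
      nf <- counts[[match(nm, names(feats))]]
      if (nf == 0L) next
      fidx <- feats[[nm]]$faces
      if (length(fidx) < nf) {
        stop(sprintf(
          "ROI too small for %d distinct strata on feature '%s': increase roi_cap_angle",
          nf, nm), call. = FALSE)
      }
      phi <- atan2(ctr[fidx, 2], ctr[fidx, 1])
      ord <- order(phi, fidx)
      fidx <- fidx[ord]
      ca <- cumsum(areas[fidx])
      total <- ca[length(ca)]
      edges <- seq(0, total, length.out = nf + 1L)
      stratum <- pmin(findInterval(ca - areas[fidx] / 2, edges,
                                   rightmost.closed = TRUE), nf)
      for (s in seq_len(nf)) {
        cand <- fidx[stratum == s]
        if (length(cand) == 0L) cand <- fidx
        f <- if (length(cand) == 1L) cand else
          sample(cand, 1L, prob = areas[cand])
        u <- runif(1); v <- runif(1)
        if (u + v > 1) { u <- 1 - u; v <- 1 - v }
        a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; cc <- V[F[f, 3], ]
        row <- row + 1L
        pts[row, ] <- a + u * (b - a) + v * (cc - a)
        faces[row] <- f
        feat_of[row] <- nm
      }
    }
  })
  list(points = pts, faces = faces, feature = feat_of, features = feats)
}

#' Generate a synthetic registration phantom
#'
#' Draws a ground-truth patient-to-CT transform, samples the dense CT-frame
#' target cloud, simulates stratified probe acquisition over the accessible
#' patch (with Gaussian tip noise and optional cartilage-like outliers
#' displaced one-sidedly off the bone along the probe-approach direction),
#' perturbs the patient-side coarse landmarks, and mounts noise-free fiducial
#' spheres 20-60 mm off the bone as the evaluation reference. All randomness
#' derives from `config$seed` through fixed sub-streams, so equal configs
#' give bit-identical phantoms.
#'
#' @param config a [phantom_config()].
#' @return A `synthetic_phantom` list: `mesh`, `target_cloud` (CT frame),
#'   `gt_transform` (patient to CT), `fiducials_ct` / `fiducials_patient`,
#'   `probe_points` (patient frame, noisy), `coarse_landmarks`
#'   (`$source` patient-side noisy, `$target` CT-side exact, `$name`),
#'   `foot_points` and `foot_faces` (true CT-frame surface correspondences of
#'   each probe point), `outlier_index`, and `config`.
#' @export
make_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  mesh <- make_bone_mesh(config$shape)

  # ground-truth rigid transform, patient -> CT
  gt <- with_seed(derive_seed(config$seed, 1), {
    ang <- runif(3, config$gt_rotation_range[1], config$gt_rotation_range[2]) * pi / 180
    tr <- runif(3, config$gt_translation_range[1], config$gt_translation_range[2])
    rigid_transform(rotation_about_z(ang[3]) %*% rotation_about_y(ang[2]) %*%
                      rotation_about_x(ang[1]), tr)
  })

  roi <- sample_roi_points(mesh, config$n_probe, config$roi_cap_angle,
                           seed = derive_seed(config$seed, 3))
  foot <- roi$points

  # The extracted CT cloud is the continuum surface; at desk scale the probed
  # foot points are included in the target cloud (within the dense_n budget)
  # so that noise-free registration has an exact zero-residual fixed point.
  n_bulk <- config$dense_n - config$n_probe
  bulk <- sample_surface(mesh, n_bulk, seed = derive_seed(config$seed, 2))
  target_cloud <- point_cloud(rbind(bulk$points, foot))

  gt_inv <- invert(gt)
  probe <- transform_points(gt_inv, foot)
  n_out <- ceiling(config$outlier_fraction * config$n_probe)
  outlier_index <- integer(0)
  probe <- with_seed(derive_seed(config$seed, 4), {
    if (n_out > 0L) {
      outlier_index <- sort(sample.int(config$n_probe, n_out))
      off <- runif(n_out, config$outlier_offset_range[1],
                   config$outlier_offset_range[2])
      for (j in seq_along(outlier_index)) {
        i <- outlier_index[j]
        dir_ct <- roi$features[[roi$feature[i]]]$void_dir(foot[i, ])
        dir_p <- as.numeric(t(gt$R) %*% dir_ct) # rotate into patient frame
        probe[i, ] <- probe[i, ] + off[j] * dir_p
      }
    }
    if (config$probe_noise_sigma > 0) {
      probe <- probe + matrix(rnorm(3 * config$n_probe, 0, config$probe_noise_sigma),
                              ncol = 3)
    }
    probe
  })

  # three well-separated coarse landmarks at fixed anatomical-style sites
  lm_target <- coarse_landmark_sites(mesh)
  lm_source <- transform_points(gt_inv, lm_target)
  lm_source <- with_seed(derive_seed(config$seed, 6), {
    lm_source + matrix(rnorm(9, 0, config$landmark_noise_sigma), ncol = 3)
  })

  # fiducial spheres 20-60 mm off the bone at spread directions around the
  # surgical target (cup centre / femoral head), noise-free
  sz <- attr(mesh, "size")
  if (config$shape == "cup") {
    bone_ctr <- c(0, 0, 0)
    bone_rad <- sz$outer_radius + sz$flange
  } else {
    bone_ctr <- sz$head_center
    bone_rad <- sz$head_radius
  }
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
                c(1, 1, -1), c(-1, -1, -1), c(1, -1, 1), c(-1, 1, 1)) / sqrt(3)
  fid_ct <- with_seed(derive_seed(config$seed, 7), {
    off <- runif(config$n_fiducials, 20, 60)
    d <- dirs[rep_len(seq_len(nrow(dirs)), config$n_fiducials), , drop = FALSE]
    sweep(d * (bone_rad + off), 2L, bone_ctr, "+")
  })
  fid_patient <- transform_points(gt_inv, fid_ct)

  structure(list(
    mesh = mesh,
    target_cloud = target_cloud,
    gt_transform = gt,
    fiducials_ct = fid_ct,
    fiducials_patient = fid_patient,
    probe_points = point_cloud(probe),
    coarse_landmarks = list(name = paste0("L", 1:3), source = lm_source,
                            target = lm_target),
    foot_points = foot,
    foot_faces = roi$faces,
    outlier_index = outlier_index,
    config = config
  ), class = "synthetic_phantom")
}

#' @export
print.synthetic_phantom <- function(x, ...) {
  cat(sprintf(
    "<synthetic_phantom> %s: %d target points, %d probe points (%d outliers), %d fiducials\n",
    x$config$shape, n_points(x$target_cloud), n_points(x$probe_points),
    length(x$outlier_index), nrow(x$fiducials_ct)))
  cat(sprintf("  probe noise sigma %.2f mm, landmark noise sigma %.2f mm, seed %d\n",
              x$config$probe_noise_sigma, x$config$landmark_noise_sigma,
              x$config$seed))
  invisible(x)
}

#' Perturb a transform by an exact rotation and translation magnitude
#'
#' Composes `gt` with a rotation of exactly `rot_deg` degrees about a
#' uniformly random axis and a translation of exactly `trans_mm` mm in a
#' uniformly random direction — a controlled imperfect initial pose for
#' solver tests. The rotation pivots about `center` (CT-frame coordinates):
#' pass the centroid of the mapped cloud so the stated magnitude measures
#' local misalignment of the surface patch rather than a lever-arm sweep
#' about the origin.
#'
#' @param gt the reference [rigid_transform()].
#' @param rot_deg rotation magnitude in degrees (>= 0).
#' @param trans_mm translation magnitude in mm (>= 0).
#' @param seed integer seed.
#' @param center rotation pivot, length-3 (default origin).
#' @return The perturbed `rigid_transform`.
#' @export
perturb_transform <- function(gt, rot_deg, trans_mm, seed = 1L,
                              center = c(0, 0, 0)) {
  stopifnot(inherits(gt, "rigid_transform"), rot_deg >= 0, trans_mm >= 0)
  center <- as.numeric(center)
  with_seed(seed, {
    axis <- rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    dR <- rotation_about_axis(axis, rot_deg * pi / 180)
    delta <- rigid_transform(dR, center - as.numeric(dR %*% center) + trans_mm * dir)
    compose(delta, gt)
  })
}
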