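#' Triangle meshes
#'
#' Minimal triangle-mesh container: `vertices` (V x 3, mm), `faces` (F x 3,
#' 1-based vertex indices), an optional per-face `regions` label (used by the
#' phantom generator to mark anatomical features), and `diagnostics` (indices
#' of degenerate, zero-area faces found on construction).
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param faces F x 3 integer matrix of vertex indices.
#' @param regions optional character vector, one label per face.
#' @return A `tri_mesh` object.
#' @export
tri_mesh <- function(vertices, faces, regions = NULL) {
  vertices <- as_points_matrix(vertices)
  faces <- as.matrix(faces)
  if (nrow(faces) > 0) {
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
    if (any(faces < 1L) || any(faces > nrow(vertices))) {
      stop(sprintf("invalid mesh: face indices outside 1..%d", nrow(vertices)),
           call. = FALSE)
    }
  } else {
    faces <- matrix(integer(0), 0, 3)
  }
  if (!all(is.finite(vertices))) stop("invalid mesh: non-finite vertex", call. = FALSE)
  if (!is.null(regions) && length(regions) != nrow(faces)) {
    stop("regions must have one label per face", call. = FALSE)
  }
  areas <- if (nrow(faces)) triangle_areas(vertices, faces) else numeric(0)
  structure(list(
    vertices = vertices,
    faces = faces,
    regions = regions,
    diagnostics = list(degenerate_faces = which(areas <= 1e-12))
  ), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$regions)) {
    cat(" | regions:", paste(unique(x$regions), collapse = ", "))
  }
  nd <- length(x$diagnostics$degenerate_faces)
  if (nd > 0) cat(sprintf(" | %d degenerate faces", nd))
  cat("\n")
  invisible(x)
}

triangle_areas <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

face_normals <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cx / pmax(sqrt(rowSums(cx^2)), .Machine$double.xmin)
}

#' Signed volume enclosed by a triangle mesh
#'
#' Divergence-theorem sum `sum v0 . (v1 x v2) / 6`; positive for outward
#' (counter-clockwise seen from outside) face winding.
#'
#' @param mesh a `tri_mesh`.
#' @return Signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Area-weighted uniform surface sampling
#'
#' Draws `n` points uniformly over the mesh surface: faces are chosen with
#' probability proportional to area, positions uniformly by barycentric
#' folding within each face. Deterministic given `seed`.
#'
#' @param mesh a `tri_mesh` with at least one non-degenerate face.
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @return A [point_cloud()]; the chosen face indices are attached as
#'   attribute `"face"`.
#' @export
sample_surface <- function(mesh, n, seed = 1L) {
  stopifnot(inherits(mesh, "tri_mesh"), n >= 1)
  if (nrow(mesh$faces) == 0L) stop("cannot sample an empty mesh", call. = FALSE)
  areas <- triangle_areas(mesh$vertices, mesh$faces)
  if (sum(areas) <= 0) stop("cannot sample a zero-area mesh", call. = FALSE)
  with_seed(seed, {
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
    u <- runif(n)
    v <- runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    pts <- a + u * (b - a) + v * (cc - a)
    out <- point_cloud(pts)
    attr(out, "face") <- fi
    out
  })
}

# --- parametric bone-like phantom surfaces ---------------------------------

# Build a quad grid patch as triangles; orient each triangle so its normal
# agrees with `outward(centroid)`.
grid_patch <- function(P, outward_fn, region, nu, nv, wrap_u = FALSE) {
  # P: function(iu, iv) -> vertex coords; iu in 0..nu (or 0..nu-1 wrapped)
  nu_v <- if (wrap_u) nu else nu + 1L
  V <- matrix(0, nu_v * (nv + 1L), 3)
  for (iv in 0:nv) {
    for (iu in 0:(nu_v - 1L)) {
      V[iv * nu_v + iu + 1L, ] <- P(iu, iv)
    }
  }
  idx <- function(iu, iv) {
    iu <- if (wrap_u) iu %% nu else iu
    iv * nu_v + iu + 1L
  }
  F <- matrix(0L, 2L * nu * nv, 3)
  fi <- 0L
  for (iv in 0:(nv - 1L)) {
    for (iu in 0:(nu - 1L)) {
      v00 <- idx(iu, iv); v10 <- idx(iu + 1L, iv)
      v01 <- idx(iu, iv + 1L); v11 <- idx(iu + 1L, iv + 1L)
      F[fi + 1L, ] <- c(v00, v10, v11)
      F[fi + 2L, ] <- c(v00, v11, v01)
      fi <- fi + 2L
    }
  }
  orient_patch(V, F, outward_fn, region)
}

orient_patch <- function(V, F, outward_fn, region) {
  keep <- triangle_areas(V, F) > 1e-12
  F <- F[keep, , drop = FALSE]
  nrm <- face_normals(V, F)
  ctr <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
          V[F[, 3], , drop = FALSE]) / 3
  out <- t(apply(ctr, 1L, outward_fn))
  flip <- rowSums(nrm * out) < 0
  F[flip, ] <- F[flip, c(1L, 3L, 2L)]
  list(V = V, F = F, region = rep(region, nrow(F)))
}

merge_patches <- function(patches) {
  off <- 0L
  V <- list(); F <- list(); reg <- list()
  for (p in patches) {
    V[[length(V) + 1L]] <- p$V
    F[[length(F) + 1L]] <- p$F + off
    reg[[length(reg) + 1L]] <- p$region
    off <- off + nrow(p$V)
  }
  tri_mesh(do.call(rbind, V), do.call(rbind, F), unlist(reg))
}

#' Parametric bone-phantom meshes
#'
#' Synthetic stand-ins for printed bone models. Two shapes:
#'
#' * `"cup"` — an acetabulum-like hemispherical shell (outer radius 27 mm,
#'   wall thickness 3 mm) with a flat rim annulus and an acetabular-notch
#'   wedge whose flat radial walls break the shell's rotational symmetry, so
#'   the probed surface constrains all six pose degrees of freedom.
#' * `"ball_shaft"` — a femur-like head sphere (radius 23 mm) on a cylindrical
#'   shaft (radius 14 mm, length 80 mm), with an oblique head resection plane
#'   (the osteotomy face probed intraoperatively) breaking the axial symmetry
#'   together with the shaft.
#'
#' Faces are labelled by feature (`regions`) so the probe simulator can
#' stratify samples over the surgically accessible patches.
#'
#' @param shape `"cup"` or `"ball_shaft"`.
#' @param size_params optional named list overriding defaults — cup:
#'   `outer_radius` (27), `thickness` (3), `notch_half_angle_deg` (20),
#'   `notch_depth_deg` (30); ball_shaft: `head_radius` (23), `shaft_radius`
#'   (14), `shaft_length` (80), `resection_frac` (0.7).
#' @param resolution angular grid steps around the axis (default 96).
#' @return A `tri_mesh` with `regions` labels and outward-consistent winding
#'   (positive signed volume).
#' @export
make_bone_mesh <- function(shape = c("cup", "ball_shaft"), size_params = list(),
                           resolution = 96L) {
  shape <- match.arg(shape)
  if (!is.list(size_params)) stop("size_params must be a list", call. = FALSE)
  if (any(unlist(size_params) <= 0)) {
    stop("mesh dimensions must be positive", call. = FALSE)
  }
  if (shape == "cup") cup_mesh(size_params, resolution)
  else ball_shaft_mesh(size_params, resolution)
}

cup_mesh <- function(sp, nphi) {
  # Single-layer articular surface, as a CT extraction of the joint surface
  # would give: a thin shell with a parallel back surface millimetres away
  # would trap nearest-neighbour correspondences under a poor initial pose.
  r_out <- sp$outer_radius %||% 27
  flange <- sp$thickness %||% 3 # rim flange width outward from the sphere edge
  notch_half <- (sp$notch_half_angle_deg %||% 22) * pi / 180
  notch_depth <- (sp$notch_depth_deg %||% 35) * pi / 180
  wall_depth <- min(sp$wall_depth %||% 13, r_out - 1)
  nphi <- max(nphi, 128L)
  ntheta <- 40L
  sph <- function(r, theta, phi) {
    r * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }
  in_notch <- function(theta, phi) {
    phi_w <- atan2(sin(phi), cos(phi)) # wrap to (-pi, pi]
    abs(phi_w) < notch_half & theta < pi / 2 + notch_depth
  }
  patches <- list()
  # The rim undulates (height h*sin(2*phi), a saddle) like the anterior /
  # posterior horns of a real acetabular rim. The undulation gives every rim
  # point a restoring point-to-plane residual against rotation about the cup
  # axis at any angle; unlike a single-period wave it is not approximated by
  # any tilted plane, so no near-null pose direction survives.
  h_rim <- sp$rim_wave %||% 9
  theta_edge <- function(phi) acos(pmin(1, pmax(-1, h_rim * sin(2 * phi) / r_out)))
  # articular sphere surface from the wavy edge down to the pole, notch removed
  pat <- grid_patch(function(iu, iv) {
    phi <- iu / nphi * 2 * pi
    te <- theta_edge(phi)
    sph(r_out, te + iv / ntheta * (pi - te), phi)
  }, function(x) x / sqrt(sum(x^2)), "inner", nphi, ntheta, wrap_u = TRUE)
  ctr <- (pat$V[pat$F[, 1], , drop = FALSE] + pat$V[pat$F[, 2], , drop = FALSE] +
          pat$V[pat$F[, 3], , drop = FALSE]) / 3
  theta_c <- acos(pmin(1, pmax(-1, ctr[, 3] / sqrt(rowSums(ctr^2)))))
  keep <- !in_notch(theta_c, atan2(ctr[, 2], ctr[, 1]))
  pat$F <- pat$F[keep, , drop = FALSE]
  pat$region <- pat$region[keep]
  patches[[length(patches) + 1L]] <- pat
  # wavy rim flange extending outward from the sphere edge, notch-interrupted
  rim <- grid_patch(function(iu, iv) {
    phi <- iu / nphi * 2 * pi
    r <- r_out * sin(theta_edge(phi)) + iv / 2 * flange
    c(r * cos(phi), r * sin(phi), h_rim * sin(2 * phi))
  }, function(x) c(0, 0, 1), "rim", nphi, 2L, wrap_u = TRUE)
  ctr <- (rim$V[rim$F[, 1], , drop = FALSE] + rim$V[rim$F[, 2], , drop = FALSE] +
          rim$V[rim$F[, 3], , drop = FALSE]) / 3
  keep <- abs(atan2(ctr[, 2], ctr[, 1])) >= notch_half
  rim$F <- rim$F[keep, , drop = FALSE]
  rim$region <- rim$region[keep]
  patches[[length(patches) + 1L]] <- rim
  # flat notch walls in the planes phi = +/- notch_half (contain the z axis):
  # the symmetry-breaking feature pinning rotation about the cup axis
  # One flat radial wall on the +phi side only: two opposing walls would be
  # mapped onto each other by a rotation of the wedge angle, re-creating a
  # discrete near-symmetry; a single wall admits no nontrivial self-map.
  nw <- 12L
  phi0 <- notch_half
  wall <- grid_patch(function(iu, iv) {
    theta <- pi / 2 + iu / nw * notch_depth
    r <- r_out - wall_depth + iv / 6 * wall_depth
    sph(r, theta, phi0)
  }, function(x) -c(-sin(phi0), cos(phi0), 0), "notch_wall",
  nw, 6L, wrap_u = FALSE) # outward points into the notch void
  patches[[length(patches) + 1L]] <- wall
  mesh <- merge_patches(patches)
  attr(mesh, "shape") <- "cup"
  attr(mesh, "size") <- list(outer_radius = r_out, flange = flange,
                             notch_half_angle = notch_half,
                             notch_depth = notch_depth)
  mesh
}

ball_shaft_mesh <- function(sp, nphi) {
  r_h <- sp$head_radius %||% 23
  r_s <- sp$shaft_radius %||% 14
  len <- sp$shaft_length %||% 80
  frac <- sp$resection_frac %||% 0.7
  if (r_s >= r_h) stop("shaft_radius must be smaller than head_radius", call. = FALSE)
  head_c <- c(0, 0, len + r_h)
  m <- c(1, 0, 0.8)
  m <- m / sqrt(sum(m^2)) # oblique resection-plane normal
  theta_cut <- acos(frac)
  # orthonormal frame with pole along m
  e1 <- c(-m[3], 0, m[1]); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(m[2] * e1[3] - m[3] * e1[2], m[3] * e1[1] - m[1] * e1[3],
          m[1] * e1[2] - m[2] * e1[1])
  ntheta <- 30L
  head <- grid_patch(function(iu, iv) {
    theta <- theta_cut + iv / ntheta * (pi - theta_cut)
    phi <- iu / nphi * 2 * pi
    d <- cos(theta) * m + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
    head_c + r_h * d
  }, function(x) (x - head_c) / sqrt(sum((x - head_c)^2)), "head",
  nphi, ntheta, wrap_u = TRUE)
  # resection disk: triangle fan in the cut plane
  r_cut <- r_h * sin(theta_cut)
  cdisk <- head_c + r_h * frac * m
  nd <- 48L
  ring <- t(vapply(0:(nd - 1L), function(i) {
    phi <- i / nd * 2 * pi
    cdisk + r_cut * (cos(phi) * e1 + sin(phi) * e2)
  }, numeric(3)))
  Vd <- rbind(cdisk, ring)
  Fd <- cbind(1L, 1L + seq_len(nd), 1L + c(seq_len(nd)[-1], 1L))
  disk <- orient_patch(Vd, Fd, function(x) m, "resection")
  nz <- 22L
  shaft <- grid_patch(function(iu, iv) {
    phi <- iu / nphi * 2 * pi
    c(r_s * cos(phi), r_s * sin(phi), iv / nz * len)
  }, function(x) c(x[1], x[2], 0) / sqrt(sum(x[1:2]^2)), "shaft",
  nphi, nz, wrap_u = TRUE)
  caps <- lapply(list(c(0, -1), c(len, 1)), function(zz) {
    ringc <- t(vapply(0:(nd - 1L), function(i) {
      phi <- i / nd * 2 * pi
      c(r_s * cos(phi), r_s * sin(phi), zz[1])
    }, numeric(3)))
    Vc <- rbind(c(0, 0, zz[1]), ringc)
    Fc <- cbind(1L, 1L + seq_len(nd), 1L + c(seq_len(nd)[-1], 1L))
    orient_patch(Vc, Fc, function(x) c(0, 0, zz[2]),
                 if (zz[2] < 0) "cap_bottom" else "cap_top")
  })
  mesh <- merge_patches(c(list(head, disk, shaft), caps))
  attr(mesh, "shape") <- "ball_shaft"
  attr(mesh, "size") <- list(head_radius = r_h, shaft_radius = r_s,
                             shaft_length = len, head_center = head_c,
                             resection_normal = m, resection_frac = frac,
                             resection_center = cdisk, theta_cut = theta_cut)
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a
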