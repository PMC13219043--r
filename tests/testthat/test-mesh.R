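test_that("tri_mesh validates indices and reports degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "face")
  m <- tri_mesh(v, rbind(c(1, 2, 3), c(1, 1, 2)))
  expect_identical(m$diagnostics$degenerate_faces, 2L)
})

test_that("area-weighted sampling is deterministic and on-surface", {
  m <- make_bone_mesh("ball_shaft")
  s1 <- sample_surface(m, 500, seed = 7)
  s2 <- sample_surface(m, 500, seed = 7)
  expect_identical(s1$points, s2$points)
  s3 <- sample_surface(m, 500, seed = 8)
  expect_false(identical(s1$points, s3$points))
  # sampled points lie on the mesh surface
  d <- navreg:::point_mesh_distance(s1$points, m)
  expect_lt(max(d), 1e-9)
})

test_that("sampling density is proportional to area across regions", {
  m <- make_bone_mesh("ball_shaft")
  s <- sample_surface(m, 20000, seed = 1)
  fid <- attr(s, "face")
  areas <- navreg:::triangle_areas(m$vertices, m$faces)
  reg_area <- tapply(areas, m$regions, sum) / sum(areas)
  reg_hits <- table(m$regions[fid]) / length(fid)
  for (rg in names(reg_area)) {
    expect_equal(as.numeric(reg_hits[[rg]]), as.numeric(reg_area[[rg]]),
                 tolerance = 0.05)
  }
})

test_that("bone meshes are well-formed", {
  for (shape in c("cup", "ball_shaft")) {
    m <- make_bone_mesh(shape)
    expect_s3_class(m, "tri_mesh")
    expect_length(m$diagnostics$degenerate_faces, 0)
    expect_gt(nrow(m$faces), 1000)
    # face normals are well-defined (no zero-area faces)
    fn <- navreg:::face_normals(m$vertices, m$faces)
    expect_true(all(is.finite(fn)))
  }
})

test_that("femoral head geometry attributes are consistent", {
  m <- make_bone_mesh("ball_shaft")
  sz <- attr(m, "size")
  # resection plane: the cut passes through resection_center with unit normal
  expect_equal(sqrt(sum(sz$resection_normal^2)), 1, tolerance = 1e-12)
  # all vertices stay on the kept side of the resection plane
  d <- sweep(m$vertices, 2, sz$head_center)
  s <- d %*% sz$resection_normal
  expect_lte(max(s), sz$head_radius * cos(sz$theta_cut) + 1e-6)
})
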