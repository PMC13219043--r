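test_that("surface metrics match hand-computed values", {
  m <- compute_surface_metrics(c(0, 3, 4))
  expect_equal(m$rmse, sqrt(25 / 3))
  expect_equal(m$max_err, 4)
  # population standard deviation about the mean 7/3
  mu <- 7 / 3
  expect_equal(m$std, sqrt(mean((c(0, 3, 4) - mu)^2)))
})

test_that("compute_tre is the mean fiducial distance", {
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  b <- rbind(c(3, 4, 0), c(10, 0, 5))  # distances 5 and 5
  expect_equal(compute_tre(a, b), 5)
  expect_equal(compute_tre(a, a), 0)
})

test_that("point_mesh_distance is exact against brute force", {
  set.seed(71)
  m <- make_bone_mesh("cup", resolution = 48)
  # near-surface probes: surface samples plus random offsets up to 3 mm
  base <- sample_surface(m, 20, seed = 71)$points
  pts <- base + matrix(rnorm(60), 20, 3)
  d <- navreg:::point_mesh_distance(pts, m)
  # brute force: min over every triangle
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  cc <- m$vertices[m$faces[, 3], , drop = FALSE]
  brute <- sapply(seq_len(nrow(pts)), function(i) {
    sqrt(min(navreg:::point_triangles_d2(pts[i, ], a, b, cc)))
  })
  expect_equal(d, brute, tolerance = 1e-10)
})

test_that("evaluate_registration reports zero error at ground truth", {
  ph <- make_phantom(phantom_config("ball_shaft", dense_n = 2000,
                                    probe_noise_sigma = 0, seed = 13))
  rep0 <- evaluate_registration(ph, ph$gt_transform)
  expect_lt(rep0$tre, 1e-9)
  expect_lt(rep0$truth$rmse, 1e-9)
  expect_identical(rep0$m_fiducials, 4L)
  # a deliberately shifted transform scores worse
  off <- rigid_transform(ph$gt_transform$R, ph$gt_transform$t + c(1, 0, 0))
  rep1 <- evaluate_registration(ph, off)
  expect_gt(rep1$tre, 0.9)
})
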