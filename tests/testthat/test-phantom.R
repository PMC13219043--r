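test_that("phantom_config validates its fields", {
  expect_error(phantom_config("cup", n_probe = 2), "n_probe")
  expect_error(phantom_config("cup", outlier_fraction = 1.2), "outlier_fraction")
  expect_error(phantom_config("cup", probe_noise_sigma = -1), "probe_noise_sigma")
  expect_error(phantom_config("nope"), "should be one of")
})

test_that("phantom generation is fully seed-deterministic", {
  cfg <- phantom_config("cup", dense_n = 3000, seed = 5)
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(a$target_cloud$points, b$target_cloud$points)
  expect_identical(a$probe_points$points, b$probe_points$points)
  expect_identical(a$gt_transform$R, b$gt_transform$R)
  expect_identical(a$fiducials_patient, b$fiducials_patient)
  cfg2 <- phantom_config("cup", dense_n = 3000, seed = 6)
  expect_false(identical(make_phantom(cfg2)$gt_transform$t, a$gt_transform$t))
})

test_that("noise-free probe points map exactly onto their foot points", {
  cfg <- phantom_config("ball_shaft", dense_n = 3000, probe_noise_sigma = 0,
                        outlier_fraction = 0, seed = 2)
  ph <- make_phantom(cfg)
  mapped <- transform_points(ph$gt_transform, ph$probe_points$points)
  expect_lt(max(abs(mapped - ph$foot_points)), 1e-9)
  # and the foot points belong to the dense target cloud
  idx <- build_spatial_index(ph$target_cloud)
  res <- query_index(idx, ph$foot_points, k = 1L)
  expect_lt(max(res$dist), 1e-9)
})

test_that("noise and outliers are applied as configured", {
  cfg <- phantom_config("ball_shaft", dense_n = 3000, probe_noise_sigma = 0.2,
                        outlier_fraction = 0.2, n_probe = 30, seed = 3)
  ph <- make_phantom(cfg)
  expect_identical(length(ph$outlier_index), 6L)  # ceiling(0.2 * 30)
  mapped <- transform_points(ph$gt_transform, ph$probe_points$points)
  err <- sqrt(rowSums((mapped - ph$foot_points)^2))
  # outliers displaced by 2-5 mm (plus noise), inliers only by the noise
  expect_true(all(err[ph$outlier_index] > 1.0))
  expect_true(all(err[-ph$outlier_index] < 1.5))
  expect_gt(max(err[ph$outlier_index]), 2.0)
})

test_that("ground-truth transform lies in the configured range", {
  for (seed in 1:5) {
    ph <- make_phantom(phantom_config("cup", dense_n = 1000, seed = seed))
    ang <- rotation_angle(ph$gt_transform$R) * 180 / pi
    # three Euler angles each in [-30, 30]: total angle below their sum
    expect_lt(ang, 90)
    expect_true(all(abs(ph$gt_transform$t) <= 50 + 1e-12))
  }
})

test_that("coarse landmarks pair patient and CT frames consistently", {
  cfg <- phantom_config("cup", dense_n = 2000, landmark_noise_sigma = 0, seed = 9)
  ph <- make_phantom(cfg)
  lm <- ph$coarse_landmarks
  expect_identical(nrow(lm$source), 3L)
  mapped <- transform_points(ph$gt_transform, lm$source)
  expect_lt(max(abs(mapped - lm$target)), 1e-9)
  # landmarks are well separated (non-degenerate triangle)
  d12 <- sqrt(sum((lm$target[1, ] - lm$target[2, ])^2))
  d13 <- sqrt(sum((lm$target[1, ] - lm$target[3, ])^2))
  d23 <- sqrt(sum((lm$target[2, ] - lm$target[3, ])^2))
  expect_gt(min(d12, d13, d23), 10)
})

test_that("fiducials transform exactly between frames", {
  ph <- make_phantom(phantom_config("ball_shaft", dense_n = 1000, seed = 4))
  mapped <- transform_points(ph$gt_transform, ph$fiducials_patient)
  expect_lt(max(abs(mapped - ph$fiducials_ct)), 1e-9)
  expect_identical(nrow(ph$fiducials_ct), 4L)
})

test_that("perturb_transform delivers the exact requested magnitudes", {
  ph <- make_phantom(phantom_config("cup", dense_n = 1000, seed = 8))
  ctr <- colMeans(ph$probe_points$points)
  pert <- perturb_transform(ph$gt_transform, rot_deg = 10, trans_mm = 10,
                           seed = 17, center = ctr)
  delta <- compose(pert, invert(ph$gt_transform))
  expect_equal(rotation_angle(delta$R) * 180 / pi, 10, tolerance = 1e-9)
  # translation magnitude measured at the rotation centre
  moved <- transform_points(delta, rbind(ctr))
  expect_equal(sqrt(sum((moved - ctr)^2)), 10, tolerance = 1e-9)
})

test_that("probe sampling restricts to the configured surgical window", {
  cfg <- phantom_config("cup", dense_n = 2000, seed = 12, roi_cap_angle = 60)
  ph <- make_phantom(cfg)
  # all cup foot points lie in the articular bowl or on the rim region
  r <- sqrt(rowSums(ph$foot_points^2))
  expect_true(all(is.finite(r)))
  expect_identical(nrow(ph$foot_points), 30L)
})
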