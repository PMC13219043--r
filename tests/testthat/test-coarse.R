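test_that("kabsch_align recovers a known transform exactly", {
  set.seed(21)
  src <- matrix(runif(15, -50, 50), 5, 3)
  A <- random_transform()
  tgt <- transform_points(A, src)
  sol <- kabsch_align(src, tgt)
  expect_s3_class(sol, "coarse_solution")
  expect_transform_equal(sol$transform, A, 1e-10)
  expect_lt(sol$rms_residual, 1e-10)
  expect_false(sol$collinear)
})

test_that("kabsch_align is least-squares optimal under noise", {
  set.seed(22)
  src <- matrix(runif(30, -50, 50), 10, 3)
  A <- random_transform()
  tgt <- transform_points(A, src) + matrix(rnorm(30, sd = 0.5), 10, 3)
  sol <- kabsch_align(src, tgt)
  base <- landmark_fre(src, tgt, sol$transform)
  # small perturbations of the optimum never reduce the residual
  for (i in 1:20) {
    dR <- exp_so3(rnorm(3, sd = 1e-3))
    pert <- rigid_transform(dR %*% sol$transform$R,
                            sol$transform$t + rnorm(3, sd = 1e-3))
    expect_gte(landmark_fre(src, tgt, pert), base)
  }
})

test_that("kabsch_align rejects degenerate input", {
  expect_error(kabsch_align(matrix(1, 2, 3), matrix(1, 2, 3)),
               "insufficient landmarks")
  collin <- cbind(1:4, 2 * (1:4), -(1:4))  # collinear points
  expect_error(kabsch_align(collin, collin + 1), "degenerate landmark geometry")
})

test_that("translation follows T = -R cs + ct", {
  set.seed(23)
  src <- matrix(runif(12, -40, 40), 4, 3)
  A <- random_transform()
  tgt <- transform_points(A, src)
  sol <- kabsch_align(src, tgt)
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  expect_equal(sol$transform$t, as.numeric(ct - sol$transform$R %*% cs),
               tolerance = 1e-10)
  # centroids are reported
  expect_equal(sol$centroid_source, cs, tolerance = 1e-12)
  expect_equal(sol$centroid_target, ct, tolerance = 1e-12)
})

test_that("landmark_fre computes the RMS alignment residual", {
  src <- diag(3) * 10
  tgt <- src
  tgt[1, 1] <- tgt[1, 1] + 3
  expect_equal(landmark_fre(src, tgt, identity_transform()), sqrt(9 / 3))
})
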