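test_that("rigid_transform validates its rotation", {
  expect_s3_class(rigid_transform(diag(3), c(1, 2, 3)), "rigid_transform")
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "rotation")
  refl <- diag(c(1, 1, -1))
  expect_error(rigid_transform(refl, c(0, 0, 0)), "rotation")
  expect_error(rigid_transform(diag(3), c(0, 0)), "translation")
})

test_that("compose and invert satisfy the group laws", {
  set.seed(11)
  for (i in 1:20) {
    A <- random_transform()
    B <- random_transform()
    p <- rnorm(3) * 50
    # (A o B) p == A (B p)
    lhs <- transform_points(compose(A, B), rbind(p))
    rhs <- transform_points(A, transform_points(B, rbind(p)))
    expect_lt(max(abs(lhs - rhs)), 1e-9)
    expect_transform_equal(compose(A, invert(A)), identity_transform(), 1e-9)
    expect_transform_equal(compose(invert(A), A), identity_transform(), 1e-9)
  }
})

test_that("apply_transform maps points affinely and normals by rotation only", {
  A <- rigid_transform(rotation_about_z(pi / 3), c(10, -5, 2))
  pts <- matrix(rnorm(30), 10, 3)
  nrm <- pts / sqrt(rowSums(pts^2))
  cl <- point_cloud(pts, nrm)
  out <- apply_transform(A, cl)
  expect_equal(out$points, t(A$R %*% t(pts) + A$t))
  expect_equal(out$normals, t(A$R %*% t(nrm)))
  # normals stay unit length
  expect_equal(rowSums(out$normals^2), rep(1, 10), tolerance = 1e-12)
})

test_that("exp_so3 matches Rodrigues and handles tiny angles", {
  # quarter turn about z
  R <- exp_so3(c(0, 0, pi / 2))
  expect_equal(R %*% c(1, 0, 0), cbind(c(0, 1, 0)), tolerance = 1e-12)
  # tiny rotation: exp([w]x) ~ I + [w]x
  w <- c(1e-10, -2e-10, 1.5e-10)
  Wx <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  expect_lt(norm(exp_so3(w) - (diag(3) + Wx), "F"), 1e-18)
  # exp(0) is the identity exactly
  expect_identical(exp_so3(c(0, 0, 0)), diag(3))
  # output is always a rotation
  set.seed(5)
  for (i in 1:10) {
    R <- exp_so3(rnorm(3))
    expect_lt(norm(t(R) %*% R - diag(3), "F"), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("rotation_angle recovers the generating angle", {
  for (th in c(0, 1e-8, 0.3, pi / 2, pi - 1e-6)) {
    expect_equal(rotation_angle(rotation_about_x(th)), th, tolerance = 1e-6)
  }
  expect_equal(rotation_angle(diag(3)), 0)
})

test_that("rotation_about_axis normalizes and matches the named helpers", {
  th <- 0.7
  expect_equal(rotation_about_axis(c(0, 0, 10), th), rotation_about_z(th),
               tolerance = 1e-12)
  expect_error(rotation_about_axis(c(0, 0, 0), 1), "axis")
})

test_that("homogeneous round trip is exact", {
  A <- random_transform()
  M <- as_homogeneous(A)
  expect_equal(dim(M), c(4L, 4L))
  expect_equal(M[4, ], c(0, 0, 0, 1))
  B <- from_homogeneous(M)
  expect_transform_equal(A, B, 1e-12)
})

test_that("orthonormalize_rotation projects a noisy matrix back to SO(3)", {
  set.seed(3)
  R <- random_rotation()
  noisy <- R + matrix(rnorm(9, sd = 1e-8), 3, 3)
  Rn <- orthonormalize_rotation(noisy)
  expect_lt(norm(t(Rn) %*% Rn - diag(3), "F"), 1e-14)
  expect_lt(norm(Rn - R, "F"), 1e-7)
})

test_that("point_cloud validates shapes and unit normals", {
  expect_error(point_cloud(matrix(1, 2, 4)), "3")
  pts <- matrix(rnorm(9), 3, 3)
  expect_error(point_cloud(pts, matrix(2, 3, 3)), "unit")
  cl <- point_cloud(pts)
  expect_identical(n_points(cl), 3L)
  sub <- subset_cloud(cl, c(1L, 3L))
  expect_identical(sub$points, pts[c(1, 3), , drop = FALSE])
})
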