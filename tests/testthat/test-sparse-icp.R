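# A compact, noise-free registration problem used by several tests.
small_problem <- function(seed = 81, dense_n = 4000) {
  cfg <- phantom_config("ball_shaft", dense_n = dense_n,
                        probe_noise_sigma = 0, outlier_fraction = 0,
                        landmark_noise_sigma = 0, seed = seed)
  ph <- make_phantom(cfg)
  target <- estimate_normals(ph$target_cloud, 30L)
  list(phantom = ph, index = build_spatial_index(target))
}

test_that("parameter constructor rejects invalid settings", {
  expect_error(sparse_icp_params(p = 1.5), "p")
  expect_error(sparse_icp_params(mu = -1), "mu")
  expect_error(sparse_icp_params(d_max = 0), "d_max")
  expect_error(sparse_icp_params(k_max = 0), "k_max")
})

test_that("sparse ICP converges from ground truth and stays there", {
  pr <- small_problem()
  res <- sparse_icp_register(pr$phantom$probe_points, pr$index,
                             pr$phantom$gt_transform, sparse_icp_params())
  met <- evaluate_registration(pr$phantom, res$transform)
  expect_lt(met$tre, 1e-6)
  expect_true(res$termination %in% c("pose_tol", "obj_tol"))
})

test_that("all fine methods refine a perturbed initialization", {
  pr <- small_problem(seed = 82)
  ctr <- colMeans(transform_points(pr$phantom$gt_transform,
                                   pr$phantom$probe_points$points))
  init <- perturb_transform(pr$phantom$gt_transform, 3, 3, seed = 1,
                            center = ctr)
  init_tre <- evaluate_registration(pr$phantom, init)$tre
  params <- sparse_icp_params()
  for (fn in list(sparse_icp_register, icp_point_to_plane, icp_point_to_point)) {
    res <- fn(pr$phantom$probe_points, pr$index, init, params)
    met <- evaluate_registration(pr$phantom, res$transform)
    expect_lt(met$tre, init_tre / 10)
    expect_lte(nrow(res$trace), params$k_max)
    expect_true(res$termination %in% c("pose_tol", "obj_tol", "max_iters"))
  }
})

test_that("the trace records a monotone-ish objective and stop reason", {
  pr <- small_problem(seed = 83)
  ctr <- colMeans(transform_points(pr$phantom$gt_transform,
                                   pr$phantom$probe_points$points))
  init <- perturb_transform(pr$phantom$gt_transform, 3, 3, seed = 2,
                            center = ctr)
  res <- sparse_icp_register(pr$phantom$probe_points, pr$index, init)
  tr <- res$trace
  expect_true(all(c("iter", "objective", "kept", "dt_norm", "dtheta_deg")
                  %in% names(tr)))
  expect_gte(nrow(tr), 1)
  # final objective no worse than the first
  expect_lte(tr$objective[nrow(tr)], tr$objective[1] + 1e-9)
})

test_that("registration is lost when no correspondences survive the gate", {
  pr <- small_problem(seed = 84, dense_n = 1000)
  far <- rigid_transform(diag(3), c(500, 500, 500))
  expect_error(
    sparse_icp_register(pr$phantom$probe_points, pr$index, far,
                        sparse_icp_params(d_max = 1.0)),
    "lost")
})

test_that("fine equals total composed with the inverse initialization", {
  pr <- small_problem(seed = 85)
  ctr <- colMeans(transform_points(pr$phantom$gt_transform,
                                   pr$phantom$probe_points$points))
  init <- perturb_transform(pr$phantom$gt_transform, 2, 2, seed = 3,
                            center = ctr)
  res <- sparse_icp_register(pr$phantom$probe_points, pr$index, init)
  expect_transform_equal(compose(res$fine, init), res$transform, 1e-9)
})

test_that("admm_inner_loop reduces the augmented objective on a fixed set", {
  pr <- small_problem(seed = 86)
  ctr <- colMeans(transform_points(pr$phantom$gt_transform,
                                   pr$phantom$probe_points$points))
  init <- perturb_transform(pr$phantom$gt_transform, 2, 2, seed = 4,
                            center = ctr)
  moved <- apply_transform(init, pr$phantom$probe_points)
  corrs <- find_correspondences(moved, pr$index, d_max = 15)
  n <- sum(corrs$kept)
  params <- sparse_icp_params(d_max = 15)
  before <- objective_value(corrs, identity_transform(), params$p)
  st <- admm_inner_loop(corrs, list(z = numeric(n), lambda = numeric(n)),
                        params)
  after <- objective_value(corrs, st$increment, params$p)
  expect_lt(after, before)
  expect_length(st$state$z, n)
  expect_length(st$state$lambda, n)
})
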