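test_that("spatial index matches a brute-force neighbour oracle", {
  set.seed(51)
  pts <- matrix(runif(900, -50, 50), 300, 3)
  cl <- point_cloud(pts)
  idx <- build_spatial_index(cl)
  queries <- rbind(matrix(runif(60, -60, 60), 20, 3),
                   pts[sample(300, 5), ])  # include exact hits
  for (k in c(1L, 5L, 12L)) {
    res <- query_index(idx, queries, k = k)
    for (q in seq_len(nrow(queries))) {
      oracle <- brute_knn(pts, queries[q, ], k)
      expect_identical(as.integer(res$idx[q, ]), oracle)
      d <- sqrt(colSums((t(pts[oracle, , drop = FALSE]) - queries[q, ])^2))
      expect_equal(as.numeric(res$dist[q, ]), d, tolerance = 1e-12)
    }
  }
})

test_that("query ties resolve to the lowest point index", {
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0))  # duplicate of row 1
  idx <- build_spatial_index(point_cloud(pts))
  res <- query_index(idx, rbind(c(1, 0, 0)), k = 2L)
  expect_identical(as.integer(res$idx[1, ]), c(1L, 3L))
})

test_that("plane normals are exact up to sign", {
  set.seed(52)
  g <- expand.grid(x = seq(-10, 10, 1), y = seq(-10, 10, 1))
  pts <- cbind(g$x, g$y, 0)
  cl <- estimate_normals(point_cloud(pts), k_neighbors = 30L)
  agree <- abs(cl$normals[, 3])
  expect_true(all(agree > 1 - 1e-6))
  expect_lt(max(abs(cl$normals[, 1:2])), 1e-6)
})

test_that("sphere normals are radial within a degree for nearly all points", {
  pts <- fib_sphere(5000, 30)
  dirs <- pts / 30
  cl <- estimate_normals(point_cloud(pts), k_neighbors = 30L)
  cosang <- abs(rowSums(cl$normals * dirs))
  frac <- mean(cosang >= cos(1 * pi / 180))
  expect_gte(frac, 0.99)
})

test_that("orient_normals_outward flips signs consistently", {
  set.seed(54)
  dirs <- matrix(rnorm(600), 200, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cl <- estimate_normals(point_cloud(dirs * 20), k_neighbors = 15L)
  out <- orient_normals_outward(cl, center = c(0, 0, 0))
  expect_true(all(rowSums(out$normals * out$points) > 0))
})

test_that("find_correspondences gates by distance and demands normals", {
  tgt <- point_cloud(rbind(c(0, 0, 0), c(10, 0, 0)))
  idx <- build_spatial_index(tgt)
  expect_error(find_correspondences(point_cloud(rbind(c(0, 0, 1))), idx),
               "normals")
  tgt <- point_cloud(tgt$points, rbind(c(0, 0, 1), c(0, 0, 1)))
  idx <- build_spatial_index(tgt)
  src <- point_cloud(rbind(c(0, 0, 1), c(10, 0, 7)))
  co <- find_correspondences(src, idx, d_max = 5)
  expect_identical(co$kept, c(TRUE, FALSE))
  expect_identical(co$target_index, c(1L, 2L))
  expect_equal(co$dist, c(1, 7))
})

test_that("crop_roi keeps points inside the sphere and warns when empty", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(5, 0, 0), c(20, 0, 0)))
  cropped <- crop_roi(cl, c(0, 0, 0), 10)
  expect_identical(n_points(cropped), 2L)
  expect_warning(crop_roi(cl, c(100, 100, 100), 1), "no points")
})

test_that("estimate_normals validates the neighbourhood size", {
  cl <- point_cloud(matrix(runif(30), 10, 3))
  expect_error(estimate_normals(cl, k_neighbors = 2L), "k_neighbors")
  expect_error(estimate_normals(cl, k_neighbors = 50L), "k_neighbors")
})
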