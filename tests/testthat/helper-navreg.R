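# Shared helpers for the test suite: random rigid transforms and
# independent oracle implementations kept deliberately naive.

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

random_transform <- function(trans_scale = 100) {
  rigid_transform(random_rotation(), runif(3, -trans_scale, trans_scale))
}

# Brute-force k nearest neighbours (squared distances, lowest-index ties)
brute_knn <- function(points, query, k) {
  d2 <- colSums((t(points) - query)^2)
  order(d2, seq_len(nrow(points)))[seq_len(k)]
}

# Quasi-uniform sphere sampling (Fibonacci lattice): a deterministic test
# surface whose normals are known exactly, so normal-estimation accuracy
# measures the estimator rather than sampling anisotropy
fib_sphere <- function(n, r) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  r * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Dense grid-search oracle for the scalar Lp proximal operator
prox_grid_oracle <- function(e, mu, p, resolution = 1e-6) {
  f <- function(z) abs(z)^p + (mu / 2) * (z - e)^2
  # minimizer lies between 0 and e; hierarchical refinement to `resolution`
  lo <- min(0, e)
  hi <- max(0, e)
  width <- hi - lo
  while (width > resolution * 200) {
    zs <- seq(lo, hi, length.out = 401)
    i <- which.min(f(zs))
    step <- zs[2] - zs[1]
    lo <- max(min(0, e), zs[i] - 2 * step)
    hi <- min(max(0, e), zs[i] + 2 * step)
    width <- hi - lo
  }
  zs <- seq(lo, hi, by = resolution)
  z <- zs[which.min(f(zs))]
  if (f(0) <= f(z)) 0 else z
}

expect_transform_equal <- function(A, B, tol = 1e-9) {
  expect_lt(norm(A$R - B$R, "F"), tol)
  expect_lt(sqrt(sum((A$t - B$t)^2)), tol)
}
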