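make_corrs <- function(n = 40, seed = 41) {
  # synthetic correspondence set with random geometry
  set.seed(seed)
  src <- matrix(runif(3 * n, -10, 10), n, 3)
  nrm <- matrix(rnorm(3 * n), n, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  tgt <- src + matrix(rnorm(3 * n, sd = 0.5), n, 3)
  structure(list(source = src, target = tgt, normal = nrm,
                 dist = sqrt(rowSums((src - tgt)^2)),
                 kept = rep(TRUE, n),
                 source_index = seq_len(n), target_index = seq_len(n),
                 d_max = Inf),
            class = "correspondence_set")
}

test_that("build_linear_system reproduces the canonical worked row", {
  corrs <- structure(list(
    source = rbind(c(1, 0, 0)), target = rbind(c(0, 0, 0)),
    normal = rbind(c(0, 0, 1)), dist = 1, kept = TRUE,
    source_index = 1L, target_index = 1L, d_max = Inf),
    class = "correspondence_set")
  sys <- build_linear_system(corrs, z = 0)
  # A = [(x cross n)^T, n^T] with x = e1, n = e3: x cross n = (0, -1, 0)
  expect_equal(as.numeric(sys$A), c(0, -1, 0, 0, 0, 1))
  # b = z - n.(x - y) = -0 (x - y has no z component... here it does not)
  expect_equal(sys$b, 0)
})

test_that("linearized prediction matches the true residual at small angles", {
  corrs <- make_corrs()
  z <- rep(0, 40)
  sys <- build_linear_system(corrs, z)
  set.seed(42)
  for (trial in 1:10) {
    omega <- rnorm(3)
    omega <- omega / sqrt(sum(omega^2)) * 1e-3   # |omega| = 1e-3
    dt <- rnorm(3, sd = 1e-3)
    xi <- c(omega, dt)
    predicted <- as.numeric(sys$A %*% xi - sys$b)
    moved <- t(exp_so3(omega) %*% t(corrs$source) + dt)
    true_res <- rowSums(corrs$normal * (moved - corrs$target)) - z
    expect_lt(max(abs(predicted - true_res)), 1e-5)
  }
})

test_that("solve_increment matches an independent QR least-squares oracle", {
  corrs <- make_corrs(seed = 43)
  z <- prox_lp(rowSums(corrs$normal * (corrs$source - corrs$target)))
  sys <- build_linear_system(corrs, z)
  inc <- solve_increment(sys, lm_damping = 0, step_cap = Inf)
  oracle <- qr.solve(qr(sys$A), sys$b)
  expect_lt(max(abs(c(inc$omega, inc$dt) - oracle)), 1e-8)
})

test_that("solve_increment caps the rotation magnitude by rescaling", {
  corrs <- make_corrs(seed = 44)
  # inflate b to force a large step
  sys <- build_linear_system(corrs, z = rep(50, 40))
  inc <- solve_increment(sys, step_cap = 0.05)
  expect_equal(sqrt(sum(inc$omega^2)), 0.05, tolerance = 1e-12)
  full <- solve_increment(sys, step_cap = Inf)
  # direction preserved for the whole 6-vector
  s <- 0.05 / sqrt(sum(full$omega^2))
  expect_equal(inc$dt, full$dt * s, tolerance = 1e-10)
})

test_that("solve_increment flags rank-deficient geometry", {
  # all points on a sphere about the origin with radial normals: every
  # rotation is in the null space of the point-to-plane system
  set.seed(45)
  nrm <- matrix(rnorm(120), 40, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  src <- nrm * 25
  corrs <- structure(list(source = src, target = src, normal = nrm,
                          dist = rep(0, 40), kept = rep(TRUE, 40),
                          source_index = 1:40, target_index = 1:40,
                          d_max = Inf),
                     class = "correspondence_set")
  sys <- build_linear_system(corrs, z = rep(0, 40))
  expect_error(solve_increment(sys, lm_damping = 0), "degenerate geometry")
})

test_that("objective_value computes sum |n.(Rx+t-y)|^p", {
  corrs <- make_corrs(seed = 46)
  r <- rowSums(corrs$normal * (corrs$source - corrs$target))
  expect_equal(objective_value(corrs, identity_transform(), p = 0.5),
               sum(abs(r)^0.5), tolerance = 1e-12)
})
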