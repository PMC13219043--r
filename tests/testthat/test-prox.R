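test_that("prox_lp handles hand-checkable cases at p = 0.5, mu = 1", {
  # small input collapses to zero; large input shrinks slightly
  expect_identical(prox_lp(0.5, 1, 0.5), 0)
  expect_equal(prox_lp(10, 1, 0.5), 9.84063, tolerance = 1e-4)
  expect_identical(prox_lp(0, 1, 0.5), 0)
  # odd symmetry
  e <- c(-12, -3, -0.8, 0.8, 3, 12)
  expect_equal(prox_lp(e, 1, 0.5), -prox_lp(-e, 1, 0.5), tolerance = 1e-12)
})

test_that("prox_lp output is never past the input and shares its sign", {
  set.seed(31)
  e <- runif(200, -20, 20)
  for (p in c(0.3, 0.5, 0.8)) {
    z <- prox_lp(e, mu = 1, p = p)
    expect_true(all(abs(z) <= abs(e) + 1e-12))
    expect_true(all(z * e >= 0))
  }
})

test_that("prox_lp matches a dense grid-search oracle on spot checks", {
  # the full sweep lives in the acceptance suite; spot-check a small set here
  set.seed(32)
  for (p in c(0.3, 0.8)) {
    for (e in c(-5, -1.2, -0.4, 0.9, 2.5, 15)) {
      z <- prox_lp(e, mu = 1.5, p = p)
      expect_equal(z, prox_grid_oracle(e, 1.5, p), tolerance = 1e-5)
    }
  }
})

test_that("prox_lp zero region is a symmetric interval", {
  e <- seq(-3, 3, by = 0.001)
  z <- prox_lp(e, mu = 1, p = 0.5)
  zero <- abs(z) < 1e-14
  # contiguous block of zeros around the origin
  idx <- which(zero)
  expect_true(all(diff(idx) == 1))
  expect_equal(min(e[zero]), -max(e[zero]), tolerance = 2e-3)
})

test_that("prox_lp validates parameters", {
  expect_error(prox_lp(1, mu = 0, p = 0.5), "mu")
  expect_error(prox_lp(1, mu = 1, p = 1), "p")
  expect_error(prox_lp(1, mu = 1, p = 0), "p")
})
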