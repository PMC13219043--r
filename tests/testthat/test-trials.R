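test_that("run_trials pairs every method against identical inputs", {
  cfg <- phantom_config("ball_shaft", dense_n = 2500, probe_noise_sigma = 0.2,
                        outlier_fraction = 0.2, seed = 1)
  tr <- run_trials(cfg, methods = c("coarse_only", "sparse_p2pl"),
                   n_repeats = 3, base_seed = 11)
  pr <- tr$per_repeat
  expect_identical(nrow(pr), 6L)
  # the checksum certifies both methods saw the same phantom per repeat
  for (i in 1:3) {
    cs <- pr$checksum[pr$repeat_id == i]
    expect_identical(cs[1], cs[2])
  }
  expect_identical(sort(unique(pr$seed)), c(11L, 12L, 13L))
  expect_identical(unname(tr$failures), c(0L, 0L))
  expect_identical(tr$summary$method, c("coarse_only", "sparse_p2pl"))
  # paired differences exist for the non-reference method
  expect_true(all(tr$paired$method == "sparse_p2pl"))
  expect_identical(nrow(tr$paired), 3L)
})

test_that("trial summaries aggregate the per-repeat metrics", {
  cfg <- phantom_config("ball_shaft", dense_n = 2500, seed = 1)
  tr <- run_trials(cfg, methods = "coarse_only", n_repeats = 4, base_seed = 3)
  d <- tr$per_repeat
  s <- tr$summary
  expect_equal(s$tre_mean, mean(d$tre))
  expect_equal(s$tre_sd, sd(d$tre))
  expect_equal(s$max_err_mean, mean(d$max_err))
})

test_that("run_trials rejects unknown methods", {
  expect_error(run_trials(methods = "fancy"), "methods")
})

test_that("the sample sweep returns one summary row per count", {
  cfg <- phantom_config("ball_shaft", dense_n = 2500, probe_noise_sigma = 0.2,
                        seed = 1)
  sw <- run_sample_sweep(cfg, counts = c(10L, 20L), n_repeats = 2,
                         base_seed = 21)
  expect_identical(sw$summary$n_probe, c(10L, 20L))
  expect_identical(nrow(sw$summary), 2L)
  expect_true(all(is.finite(sw$summary$tre_mean)))
})

test_that("register_pipeline runs end to end on a phantom", {
  cfg <- phantom_config("ball_shaft", dense_n = 4000, probe_noise_sigma = 0.1,
                        seed = 31)
  ph <- make_phantom(cfg)
  out <- register_pipeline(ph$probe_points, ph$target_cloud,
                           ph$coarse_landmarks, method = "sparse_p2pl")
  expect_s3_class(out$total, "rigid_transform")
  coarse_tre <- evaluate_registration(ph, out$coarse$transform)$tre
  fine_tre <- evaluate_registration(ph, out$total)$tre
  expect_lt(fine_tre, coarse_tre)
  expect_lte(out$n_target, 4000)
})
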