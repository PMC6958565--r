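test_that("cohort generation is deterministic under a fixed seed", {
  c1 <- make_cohort(1, 1, seed = 9)
  c2 <- make_cohort(1, 1, seed = 9)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$configured, c2$configured)
  s1 <- rasterize_cine(c1$subjects[[1]]$planes[[1]]$vessels,
                       c1$subjects[[1]]$planes[[1]]$acq)
  s2 <- rasterize_cine(c2$subjects[[1]]$planes[[1]]$vessels,
                       c2$subjects[[1]]$planes[[1]]$acq)
  expect_identical(s1$stack$velocity, s2$stack$velocity)
})

test_that("zero group SDs make every subject identical to the group mean", {
  cfg <- cohort_config(noise_sigma = 0)
  cfg$group_params$HYV_sd <- 0
  cfg$group_params$HEV_sd <- 0
  co <- make_cohort(3, 1, seed = 10, config = cfg)
  hyv <- co$truth[co$truth$group == "HYV", ALL_METRICS]
  for (nm in ALL_METRICS)
    expect_equal(stats::sd(hyv[[nm]]), 0, tolerance = 1e-12, label = nm)
  gp <- cfg$group_params
  expect_equal(hyv$extra_acbf[1], gp$HYV_mean[gp$param == "extra_acbf"],
               tolerance = 1e-9)
  expect_equal(hyv$extra_arterial_pi[1],
               gp$HYV_mean[gp$param == "extra_arterial_pi"], tolerance = 1e-6)
})

test_that("16+19 cohort reproduces the configured arterial group means", {
  co <- make_cohort(16, 19, seed = 12)
  for (g in c("HYV", "HEV")) {
    target <- if (g == "HYV") 716 else 588
    v <- co$truth$extra_acbf[co$truth$group == g]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), 2 * se)
  }
})

test_that("positivity redraws keep all drawn quantities physiological", {
  co <- make_cohort(8, 8, seed = 13)
  cfgd <- co$configured
  for (nm in setdiff(names(cfgd), c("subject", "group")))
    expect_true(all(cfgd[[nm]] > 0), label = nm)
  expect_true(all(cfgd$heart_rate >= 45 & cfgd$heart_rate <= 100))
})

test_that("generator truth equals closed-form metric values where known", {
  co <- make_cohort(4, 4, seed = 14)
  # arterial PI of each tree equals the drawn PI (shape normalisation)
  expect_equal(co$truth$extra_arterial_pi, co$configured$extra_arterial_pi,
               tolerance = 1e-9)
  expect_equal(co$truth$intra_arterial_pi, co$configured$intra_arterial_pi,
               tolerance = 1e-9)
  # composite flows equal the drawn composite means
  expect_equal(co$truth$extra_acbf, co$configured$extra_acbf, tolerance = 1e-9)
  expect_equal(co$truth$intra_vcbf, co$configured$intra_vcbf, tolerance = 1e-9)
  # spinal CSF SV tracks its sinusoid target to discretization error
  expect_equal(co$truth$spinal_csf_sv, co$configured$spinal_csf_sv,
               tolerance = 0.01)
  # venous synthesis hits the drawn venous PI / blood SV pair for most
  # subjects (draw combinations outside the waveform model's reachable set
  # clamp, and then truth records the realized value)
  pi_resid <- abs(co$truth$intra_venous_pi - co$configured$intra_venous_pi) /
    co$configured$intra_venous_pi
  expect_lt(median(pi_resid), 0.02)
  sv_resid <- abs(co$truth$intra_blood_sv - co$configured$intra_blood_sv) /
    co$configured$intra_blood_sv
  expect_lt(median(sv_resid), 0.25)
})
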