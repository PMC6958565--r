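test_that("flow curve conversion uses 1 cm/s x 1 mm^2 = 0.6 ml/min", {
  fc <- flow_curve(rep(10, 32), 25, 0.9)
  expect_true(all(fc$samples == 150))
  expect_true(all(flow_curve(rep(0, 32), 25, 0.9)$samples == 0))
  expect_error(flow_curve(rep(1, 32), 0, 0.9), "area")
})

test_that("composite flows sum the correct vessel sets", {
  mk <- function(val) flow_curve(rep(val, 32), 1 / 0.6, 0.9)  # val ml/min
  curves <- list(ICA_L = mk(100), ICA_R = mk(100), VA_L = mk(100),
                 VA_R = mk(100), BA = mk(80), IJV_L = mk(150),
                 IJV_R = mk(150), SSS = mk(200), StrS = mk(90))
  extra <- compose_flows(curves, "extra")
  expect_equal(extra$arterial$samples, rep(400, 32))
  expect_equal(extra$venous$samples, rep(300, 32))
  intra <- compose_flows(curves, "intra")
  expect_equal(intra$arterial$samples, rep(280, 32))   # 3 vessels, no VAs
  expect_equal(intra$venous$samples, rep(290, 32))
  # permuting the list leaves sums unchanged
  perm <- compose_flows(curves[sample(names(curves))], "extra")
  expect_equal(perm$arterial$samples, extra$arterial$samples)
  # missing vessel is named
  expect_error(compose_flows(curves[names(curves) != "VA_R"], "extra"), "VA_R")
})

test_that("alpha correction balances the venous mean to the arterial mean", {
  a <- flow_curve(rep(10, 32), 100, 0.9)                 # mean 600
  v <- flow_curve(10 + 3 * sin(2 * pi * (0:31) / 32), 100 / 1.5, 0.9)  # mean 400
  ac <- alpha_correction(a, v)
  expect_equal(ac$alpha, 1.5, tolerance = 1e-12)
  expect_equal(mean(ac$theoretical_vcbf$samples), 600, tolerance = 1e-9)
  # identity when means are equal
  ac2 <- alpha_correction(a, a)
  expect_equal(ac2$alpha, 1)
  expect_equal(ac2$theoretical_vcbf$samples, a$samples)
  # ratio of the reference young-group composite means; note this
  # ratio-of-means (1.594) is not the cohort mean of per-subject ratios
  # (1.67), which averages individual alphas
  a3 <- flow_curve(rep(716 / 0.6, 32), 1, 0.9)
  v3 <- flow_curve(rep(449 / 0.6, 32), 1, 0.9)
  expect_equal(alpha_correction(a3, v3)$alpha, 716 / 449, tolerance = 1e-9)
  expect_equal(716 / 449, 1.5946, tolerance = 1e-4)
  expect_error(alpha_correction(a, flow_curve(rep(-1, 32), 1, 0.9)),
               "non-positive")
})

test_that("arteriovenous flow is the pointwise difference with zero mean", {
  t32 <- (0:31) / 32
  a <- flow_curve(10 + 2 * sin(2 * pi * t32), 50, 0.9)
  flat <- flow_curve(rep(10, 32), 50, 0.9)
  av <- arteriovenous_flow(a, flat)
  expect_equal(av$samples, 2 * 50 * 0.6 * sin(2 * pi * t32), tolerance = 1e-12)
  expect_equal(arteriovenous_flow(a, a)$samples, rep(0, 32))
  expect_error(arteriovenous_flow(a, flow_curve(rep(1, 16), 50, 0.9)),
               "mismatched")
})

test_that("alpha-corrected arteriovenous mean vanishes over a seeded cohort", {
  co <- make_cohort(5, 5, seed = 21)
  for (scene in co$subjects) {
    for (level in c("extra", "intra")) {
      plane <- if (level == "extra") "extracranial_vessels" else "intracranial_vessels"
      comp <- compose_flows(scene$true_curves[[plane]], level)
      ac <- alpha_correction(comp$arterial, comp$venous)
      av <- arteriovenous_flow(comp$arterial, ac$theoretical_vcbf)
      expect_lt(abs(mean(av$samples)), 1e-9 * mean(comp$arterial$samples))
    }
  }
})

test_that("blood stroke volume matches the sinusoid closed form A T / pi", {
  T <- 0.9; A <- 5                                        # ml/s
  av <- flow_curve(A * 60 / (50 * 0.6) * sin(2 * pi * (0:31) / 32), 50, T)
  sv <- blood_stroke_volume(av)
  expect_equal(sv, A * T / pi, tolerance = 0.01)
  expect_equal(blood_stroke_volume(flow_curve(rep(0, 32), 50, T)), 0)
  # linearity: doubling amplitude doubles SV
  av2 <- flow_curve(2 * A * 60 / (50 * 0.6) * sin(2 * pi * (0:31) / 32), 50, T)
  expect_equal(blood_stroke_volume(av2), 2 * sv, tolerance = 1e-12)
})

test_that("stroke volumes are invariant under cyclic rotation of samples", {
  t32 <- (0:31) / 32
  av <- flow_curve(3 * sin(2 * pi * t32) + sin(4 * pi * t32), 50, 0.9)
  sv0 <- blood_stroke_volume(av)
  csf0 <- suppressWarnings(csf_stroke_volume(av))
  for (k in c(5, 12, 27)) {
    rot <- av
    rot$samples <- av$samples[c((k + 1):32, 1:k)]
    expect_equal(blood_stroke_volume(rot), sv0, tolerance = 1e-12)
    expect_equal(as.numeric(suppressWarnings(csf_stroke_volume(rot))),
                 as.numeric(csf0), tolerance = 1e-12)
  }
})

test_that("CSF stroke volume matches sinusoid lobe area a T / pi", {
  T <- 1; a <- 1                                          # ml/s
  q <- flow_curve(a * 60 * sin(2 * pi * (0:31) / 32), 1 / 0.6, T)
  sv <- csf_stroke_volume(q)
  expect_equal(as.numeric(sv), a * T / pi, tolerance = 0.01)
  expect_false(attr(sv, "unidirectional"))
  expect_equal(as.numeric(blood_stroke_volume(flow_curve(rep(0, 32), 1, T))), 0)
})

test_that("asymmetric two-lobe CSF curve matches a fine-grid oracle", {
  T <- 0.85
  f <- function(t) 2 * sin(2 * pi * t / T) + 0.8 * sin(4 * pi * t / T) - 0.3
  expected <- csf_sv_oracle(f, T)
  q32 <- f((0:31) / 32 * T) * 60                          # ml/min
  sv <- suppressWarnings(csf_stroke_volume(flow_curve(q32, 1 / 0.6, T)))
  expect_equal(as.numeric(sv), expected, tolerance = 0.01)
})

test_that("unidirectional CSF curves are computed but flagged", {
  q <- flow_curve(rep(6, 32), 10, 0.9)
  expect_warning(sv <- csf_stroke_volume(q), "unidirectional")
  expect_true(attr(sv, "unidirectional"))
  expect_gt(as.numeric(sv), 0)
})

test_that("pulsatility index follows (max - min) / mean on raw samples", {
  q <- flow_curve(c(rep(2, 16), rep(10, 15), 6) / 0.6, 1, 0.9)
  expect_equal(pulsatility_index(q), (10 - 2) / mean(q$samples * 1))
  expect_equal(pulsatility_index(flow_curve(rep(7, 32), 1, 0.9)), 0)
  s <- flow_curve(600 + 300 * sin(2 * pi * (0:31) / 32), 1 / 0.6, 0.9)
  expect_equal(pulsatility_index(s), 2 * 300 / 600, tolerance = 1e-12)
  # invariant under positive scaling and period change
  s2 <- s; s2$samples <- 3.7 * s$samples; s2$cardiac_period <- 1.2
  expect_equal(pulsatility_index(s2), pulsatility_index(s), tolerance = 1e-12)
  expect_error(pulsatility_index(flow_curve(c(-1, 1, rep(0, 30)), 1, 0.9)),
               "zero-mean")
})
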