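test_that("noise-free disk lumen is segmented pixel-for-pixel", {
  ras <- single_vessel_scene(600, 300, noise_sigma = 0)
  roi <- segment_roi(ras$stack, c(33L, 33L), "ICA_L", -1)
  expect_setequal(roi$pixels, ras$rois$ICA_L$pixels)
})

test_that("anti-phase adjacent lumen is excluded from the grown region", {
  w1 <- waveform_spec(300, 150, phase_offset = 0)
  w2 <- waveform_spec(300, 150, phase_offset = 0.5)   # anti-phase
  v1 <- vessel_spec("ICA_L", c(-2.2, 0), 12, 1, w1)
  v2 <- vessel_spec("ICA_R", c(2.2, 0), 12, 1, w2)
  acq <- acquisition_spec(matrix = c(48L, 48L), noise_sigma = 0)
  ras <- rasterize_cine(list(v1, v2), acq)
  seed <- c(round(-2.2 / 0.55 + 24.5), 25L)
  roi <- segment_roi(ras$stack, seed, "ICA_L", 1)
  # exhaustive pixel check: mask equals lumen 1 and excludes all of lumen 2
  expect_setequal(roi$pixels, ras$rois$ICA_L$pixels)
  expect_length(intersect(roi$pixels, ras$rois$ICA_R$pixels), 0)
})

test_that("seeding in static background raises a pulsatility error", {
  ras <- single_vessel_scene(600, 300, noise_sigma = 0)
  expect_error(segment_roi(ras$stack, c(5L, 5L), "ICA_L", -1),
               "no pulsatile signal at seed")
})

test_that("segmentation under noise recovers the lumen almost completely", {
  ras <- single_vessel_scene(600, 300, noise_sigma = 0.4, seed = 3L)
  roi <- segment_roi(ras$stack, c(33L, 33L), "ICA_L", -1)
  truth <- ras$rois$ICA_L$pixels
  expect_gte(length(intersect(roi$pixels, truth)) / length(truth), 0.95)
  expect_lte(length(setdiff(roi$pixels, truth)), 2)
})

test_that("magnitude flood fill recovers the bright lumen", {
  ras <- single_vessel_scene(600, 300, noise_sigma = 0.4, seed = 4L)
  px <- magnitude_roi(ras$stack, c(33L, 33L))
  expect_setequal(px, ras$rois$ICA_L$pixels)
})

test_that("mean velocity curve averages the ROI with the direction sign", {
  ras <- single_vessel_scene(600, 300, noise_sigma = 0, sign = -1)
  mv <- mean_velocity_curve(ras$stack, ras$rois$ICA_L)
  expect_true(all(mv$velocity > 0))            # sign re-applied
  # half lumen at 2v, half at 0 averages to v
  nx <- 8L; nf <- 8L
  vel <- array(0, c(nx, nx, nf))
  px <- 1:10
  for (t in seq_len(nf)) { f <- vel[, , t]; f[px[1:5]] <- 12; vel[, , t] <- f }
  stack <- cine_stack(vel, array(1, dim(vel)), 80, 0.9, 0.55)
  mv2 <- mean_velocity_curve(stack, roi_mask("ICA_L", px, 1, c(nx, nx)))
  expect_equal(mv2$velocity, rep(6, nf))
})

test_that("mean velocity curve is linear in the velocity data", {
  ras <- single_vessel_scene(600, 300, noise_sigma = 0.4, seed = 5L)
  roi <- ras$rois$ICA_L
  mv1 <- mean_velocity_curve(ras$stack, roi)
  st2 <- ras$stack
  st2$velocity <- 2 * st2$velocity + 1
  mv2 <- mean_velocity_curve(st2, roi)
  expect_equal(mv2$velocity, 2 * mv1$velocity + roi$direction_sign * 1,
               tolerance = 1e-12)
})

test_that("noisy ROI mean is within the standard-error bound per frame", {
  sigma <- 0.4
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    ras <- single_vessel_scene(600, 300, noise_sigma = sigma, seed = s)
    roi <- ras$rois$ICA_L
    mv <- mean_velocity_curve(ras$stack, roi)
    truth <- ras$truth$curves[, 1] / (ras$truth$areas[[1]] * 0.6)
    se <- sigma / sqrt(length(roi$pixels))
    err <- abs(mv$velocity - truth)
    hits <- hits + sum(err <= 3 * se)
    total <- total + length(err)
  }
  expect_gte(hits / total, 0.99)
})

test_that("flow measurement repeatability across noise realizations is < 5%", {
  flows <- vapply(1:20, function(s) {
    ras <- single_vessel_scene(600, 300, noise_sigma = NULL, seed = 100L + s)
    quantify_single_vessel(ras)
  }, numeric(1))
  nsd <- 100 * stats::sd(flows) / mean(flows)
  expect_lt(nsd, 5)
})
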