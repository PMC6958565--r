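test_that("phase wrap maps velocities into (-venc, venc] as expected", {
  expect_equal(apply_phase_wrap(90, 80), -70)
  expect_equal(apply_phase_wrap(-90, 80), 70)
  expect_equal(apply_phase_wrap(50, 80), 50)
  expect_equal(apply_phase_wrap(80, 80), 80)    # boundary stays at +venc
  expect_equal(apply_phase_wrap(-80, 80), 80)   # -venc maps to +venc
  v <- seq(-200, 200, by = 0.37)
  w <- apply_phase_wrap(v, 80)
  expect_true(all(w > -80 & w <= 80))
  inside <- abs(v) <= 80 & v != -80
  expect_equal(w[inside], v[inside])
})

test_that("single-wrap correction has the right sign and magnitude", {
  expect_equal(correct_aliasing(-70, 80), 90)
  expect_equal(correct_aliasing(70, 80), -90)
  expect_equal(correct_aliasing(-4, 5), 6)
  expect_warning(out <- correct_aliasing(0, 80), "zero stored velocity")
  expect_equal(out, 0)
})

test_that("wrap followed by correction recovers truth for venc < |v| < 2 venc", {
  venc <- 80
  v <- c(seq(80.01, 159.99, length.out = 500),
         seq(-159.99, -80.01, length.out = 500))
  rec <- correct_aliasing(apply_phase_wrap(v, venc), venc)
  expect_equal(rec, v, tolerance = 1e-12)
  # CSF venc too
  v2 <- seq(5.01, 9.99, length.out = 200)
  expect_equal(correct_aliasing(apply_phase_wrap(v2, 5), 5), v2,
               tolerance = 1e-12)
})

test_that("aliased-pixel detector counts fractions and applies the 50% rule", {
  # hand-built stack: 10-pixel lumen, velocities set per frame
  nx <- 8L; ny <- 8L; nf <- 4L
  vel <- array(0, c(nx, ny, nf))
  px <- as.integer(c(19:23, 27:31))          # 10 pixels
  roi <- roi_mask("ICA_L", px, direction_sign = 1, dim = c(nx, ny))
  stack <- cine_stack(vel, array(1, c(nx, ny, nf)), venc = 80,
                      cardiac_period = 0.9, pixel_spacing = 0.55)
  # frame 1: no wrapped pixels
  stack$velocity[, , 1] <- 0
  for (p in px) stack$velocity[, , 1][p] <- 30
  det <- detect_aliasing(stack, roi)
  expect_equal(det$fraction[1], 0)
  # frame 2: 6 of 10 pixels wrapped (stored -75, opposing +1, |v| > 60)
  f2 <- stack$velocity[, , 2]
  f2[px] <- 30; f2[px[1:6]] <- -75
  stack$velocity[, , 2] <- f2
  det <- detect_aliasing(stack, roi)
  # brute-force count oracle
  manual <- mean(f2[px] < 0 & abs(f2[px]) > 0.75 * 80)
  expect_equal(det$fraction[2], manual)
  expect_equal(det$fraction[2], 0.6)
  expect_true(det$reject)
  # exactly 50% flagged in the worst frame -> accepted (strict > 0.5)
  f2[px] <- 30; f2[px[1:5]] <- -75
  stack$velocity[, , 2] <- f2
  det <- detect_aliasing(stack, roi)
  expect_equal(max(det$fraction), 0.5)
  expect_false(det$reject)
  expect_error(detect_aliasing(stack, roi_mask("ICA_L", integer(0), 1, c(nx, ny))),
               "empty ROI")
})

test_that("dealias_roi corrects exactly the flagged pixels", {
  ras <- single_vessel_scene(mean_flow = 1340, amplitude = 0, area = 25,
                             venc = 80, sign = 1)
  # 1340 ml/min over the rasterized area gives ~90 cm/s -> wraps to ~-70
  true_v <- unname(ras$truth$curves[1, 1] / (ras$truth$areas[[1]] * 0.6))
  expect_gt(true_v, 80); expect_lt(true_v, 160)
  stored <- ras$stack$velocity[, , 1][ras$rois$ICA_L$pixels]
  expect_true(all(stored < 0))                 # wrapped to the opposite sign
  st <- dealias_roi(ras$stack, ras$rois$ICA_L, force = TRUE)
  rec <- st$velocity[, , 1][ras$rois$ICA_L$pixels]
  expect_equal(rec, rep(true_v, length(rec)), tolerance = 1e-12)
})
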