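# 4-connected neighbours of a linear pixel index in an nx x ny grid.
neighbours4 <- function(idx, nx, ny) {
  i <- ((idx - 1L) %% nx) + 1L
  j <- ((idx - 1L) %/% nx) + 1L
  out <- integer(0)
  if (i > 1L)  out <- c(out, idx - 1L)
  if (i < nx)  out <- c(out, idx + 1L)
  if (j > 1L)  out <- c(out, idx - nx)
  if (j < ny)  out <- c(out, idx + nx)
  out
}

# Cyclic boxcar smoothing of per-pixel waveforms (rows of an n_px x n_frames
# matrix); width 1 is a no-op.
smooth_waveforms <- function(vm, width = 1L) {
  if (width <= 1L) return(vm)
  nf <- ncol(vm)
  half <- (width - 1L) %/% 2L
  out <- vm
  for (k in seq_len(half)) {
    out <- out + vm[, c((k + 1):nf, 1:k), drop = FALSE] +
                 vm[, c((nf - k + 1):nf, 1:(nf - k)), drop = FALSE]
  }
  out / (2L * half + 1L)
}

# Temporal standard deviation of every row of a waveform matrix.
row_temporal_sd <- function(vm) {
  mu <- rowMeans(vm)
  sqrt(rowSums((vm - mu)^2) / (ncol(vm) - 1L))
}

#' Provisional lumen mask from the magnitude image
#'
#' Flood-fills 4-connected pixels whose time-averaged magnitude exceeds
#' `threshold` times the seed pixel's magnitude. Used to obtain a
#' provisional ROI for aliasing detection before waveform-based
#' segmentation is possible (wrapped waveforms correlate poorly).
#'
#' @param stack a [cine_stack()].
#' @param seed_pixel integer length-2 `(i, j)` pixel coordinates.
#' @param threshold admission threshold as a fraction of seed magnitude.
#' @return Integer vector of linear pixel indices.
#' @export
magnitude_roi <- function(stack, seed_pixel, threshold = 0.5) {
  nx <- dim(stack$magnitude)[1]; ny <- dim(stack$magnitude)[2]
  seed <- (seed_pixel[2] - 1L) * nx + seed_pixel[1]
  if (seed < 1L || seed > nx * ny) stop("seed pixel outside image")
  m <- rowMeans(matrix(stack$magnitude, nx * ny, stack$n_frames))
  gate <- threshold * m[seed]
  inmask <- logical(nx * ny)
  inmask[seed] <- TRUE
  queue <- seed
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in neighbours4(cur, nx, ny)) {
      if (!inmask[nb] && m[nb] >= gate) {
        inmask[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  which(inmask)
}

#' Segment a pulsatile lumen by waveform-correlation region growing
#'
#' Deterministic stand-in for semi-automated flow-based segmentation: grow a
#' 4-connected region from a seed pixel, admitting a neighbour when (a) its
#' temporal velocity standard deviation exceeds a pulsatility floor, and
#' (b) its velocity-versus-time waveform has Pearson correlation at least
#' `r_min` with the running ROI-mean waveform. Growth is breadth-first in a
#' fixed pixel order, so the result is reproducible.
#'
#' Both admission statistics are computed on cyclically boxcar-smoothed
#' waveforms (width `smooth`, default 5 of 32 frames): a matched-filter step
#' that suppresses frame-to-frame noise while preserving the cardiac
#' waveform, keeping weakly pulsatile lumens (low-pulsatility venous
#' sinuses) above the detection gates. The quantified ROI-mean curve itself
#' is always taken from the raw data.
#'
#' The pulsatility floor defaults to `1.25 x` the median smoothed temporal
#' SD over all pixels: with background-dominated images the median estimates
#' the noise floor, so static tissue is excluded while genuinely pulsatile
#' pixels (whose SD carries the flow waveform on top of the noise) pass.
#' The stack must be de-aliased first ([dealias_roi()]): a wrapped pixel's
#' waveform decorrelates from its lumen.
#'
#' @param stack a [cine_stack()] (de-aliased).
#' @param seed_pixel integer length-2 `(i, j)` pixel coordinates inside the
#'   target lumen.
#' @param label vessel label for the returned mask.
#' @param direction_sign the vessel's flow direction (+1/-1).
#' @param r_min minimum Pearson correlation with the running ROI mean
#'   waveform (default 0.7).
#' @param pulsatility_floor temporal-SD floor in cm/s, or `NULL` for the
#'   median-based default.
#' @param smooth cyclic boxcar width (frames) for the admission statistics;
#'   1 disables smoothing.
#' @param max_pixels growth cap (guards against runaway admission).
#' @return A [roi_mask()] containing the seed.
#' @export
segment_roi <- function(stack, seed_pixel, label, direction_sign = 1,
                        r_min = 0.7, pulsatility_floor = NULL,
                        smooth = 5L, max_pixels = 5000L) {
  stopifnot(inherits(stack, "cine_stack"))
  nx <- dim(stack$velocity)[1]; ny <- dim(stack$velocity)[2]
  nf <- stack$n_frames
  seed <- (seed_pixel[2] - 1L) * nx + seed_pixel[1]
  if (seed_pixel[1] < 1L || seed_pixel[1] > nx ||
      seed_pixel[2] < 1L || seed_pixel[2] > ny)
    stop("seed pixel outside image")

  vm_raw <- matrix(stack$velocity, nx * ny, nf)
  vm <- smooth_waveforms(vm_raw, smooth)
  sds <- row_temporal_sd(vm)
  if (is.null(pulsatility_floor)) pulsatility_floor <- 1.25 * stats::median(sds)

  if (sds[seed] <= pulsatility_floor)
    stop("no pulsatile signal at seed")

  inmask <- logical(nx * ny)
  rejected <- logical(nx * ny)
  inmask[seed] <- TRUE
  mean_wave <- vm[seed, ]
  n_in <- 1L
  queue <- seed
  while (length(queue) && n_in < max_pixels) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in neighbours4(cur, nx, ny)) {
      if (inmask[nb] || rejected[nb]) next
      if (sds[nb] <= pulsatility_floor) { rejected[nb] <- TRUE; next }
      r <- suppressWarnings(stats::cor(vm[nb, ], mean_wave))
      if (!is.na(r) && r >= r_min) {
        inmask[nb] <- TRUE
        mean_wave <- (mean_wave * n_in + vm[nb, ]) / (n_in + 1L)
        n_in <- n_in + 1L
        queue <- c(queue, nb)
      } else {
        rejected[nb] <- TRUE
      }
    }
  }
  roi_mask(label, which(inmask), direction_sign, c(nx, ny))
}

#' Mean-velocity waveform of a region of interest
#'
#' Per-frame arithmetic mean of `direction_sign * velocity` over the ROI
#' pixels, so the returned curve is positive in the vessel's own flow
#' direction, plus the ROI area.
#'
#' @param stack a [cine_stack()] (de-aliased).
#' @param roi a [roi_mask()].
#' @return List with `velocity` (cm/s, one value per frame) and `area`
#'   (mm^2 = pixel count x pixel area).
#' @export
mean_velocity_curve <- function(stack, roi) {
  stopifnot(inherits(stack, "cine_stack"), inherits(roi, "roi_mask"))
  if (length(roi$pixels) == 0L) stop("empty ROI")
  v <- roi_velocity_matrix(stack, roi)
  list(velocity = roi$direction_sign * colMeans(v),
       area = length(roi$pixels) * stack$pixel_area)
}
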