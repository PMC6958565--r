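#' Construct a cine stack object
#'
#' Container for one cardiac-gated velocity + magnitude cine series:
#' `velocity` and `magnitude` are `nx x ny x n_frames` arrays, velocities in
#' cm/s with the cranio-caudal-positive sign convention and already wrapped
#' into `(-venc, +venc]`.
#'
#' @param velocity,magnitude numeric arrays, `nx x ny x n_frames`.
#' @param venc velocity encoding, cm/s.
#' @param cardiac_period cycle duration, s.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @param plane_label one of [PLANE_LABELS].
#' @return An object of class `cine_stack`.
#' @export
cine_stack <- function(velocity, magnitude, venc, cardiac_period,
                       pixel_spacing, slice_thickness = 5,
                       plane_label = "extracranial_vessels") {
  stopifnot(is.array(velocity), length(dim(velocity)) == 3L,
            identical(dim(velocity), dim(magnitude)))
  plane_label <- match.arg(plane_label, PLANE_LABELS)
  structure(list(velocity = velocity, magnitude = magnitude,
                 venc = venc, cardiac_period = cardiac_period,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 pixel_area = pixel_spacing^2,
                 n_frames = dim(velocity)[3],
                 plane_label = plane_label),
            class = "cine_stack")
}

#' Construct a region-of-interest mask
#'
#' @param label vessel/CSF label (one of [VESSEL_LABELS]).
#' @param pixels integer vector of linear pixel indices into an
#'   `nx x ny` image plane.
#' @param direction_sign +1 / -1, the vessel's flow direction in the
#'   cranio-caudal-positive convention.
#' @param dim integer length-2 image dimensions the indices refer to.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(label, pixels, direction_sign, dim) {
  label <- match.arg(label, VESSEL_LABELS)
  if (length(pixels) == 0L) stop("empty ROI")
  if (any(pixels < 1L | pixels > prod(dim))) stop("ROI pixels out of bounds")
  if (!direction_sign %in% c(-1, 1)) stop("direction_sign must be +1 or -1")
  structure(list(label = label, pixels = as.integer(pixels),
                 direction_sign = direction_sign, dim = as.integer(dim)),
            class = "roi_mask")
}

# n_pixels x n_frames matrix of stored velocities over the ROI.
roi_velocity_matrix <- function(stack, roi) {
  nf <- stack$n_frames
  npx <- prod(dim(stack$velocity)[1:2])
  vm <- matrix(stack$velocity, nrow = npx, ncol = nf)
  vm[roi$pixels, , drop = FALSE]
}

#' Rasterize a scene of pulsatile lumens into a cine stack
#'
#' Each vessel's volumetric flow waveform is converted to a spatially
#' uniform lumen velocity `v(t) = Q(t) / (A_pix * 0.6)` cm/s, where `A_pix`
#' is the area actually covered by the rasterized pixel set (pixel count x
#' pixel area, mm^2) - so that ROI mean velocity times ROI area reproduces
#' the waveform exactly. The stored phase image carries
#' `direction_sign * v(t)` plus Gaussian velocity noise, wrapped into
#' `(-venc, +venc]`. The magnitude image is bright (1) inside lumens and dim
#' (0.05) outside.
#'
#' With `partial_volume = TRUE` a one-pixel ring outside each lumen carries
#' half the lumen velocity, emulating the partial-volume contamination that
#' protocol design (pixel size, slice orientation) is meant to avoid.
#'
#' @param vessels list of [vessel_spec()]; lumens must not overlap and must
#'   fit inside the matrix.
#' @param acq an [acquisition_spec()]; `acq$seed` seeds the noise stream.
#' @param partial_volume logical; add the partial-volume ring (default FALSE).
#' @param plane_label plane label stored in the stack (one of [PLANE_LABELS]).
#' @return List with `stack` (a [cine_stack()]), `rois` (list of
#'   [roi_mask()], the true rasterized lumens) and `truth` (a `ground_truth`
#'   list: per-vessel true flow curves in ml/min, rasterized areas, and
#'   per-vessel mean flow / PI / stroke volume).
#' @export
rasterize_cine <- function(vessels, acq, partial_volume = FALSE,
                           plane_label = "extracranial_vessels") {
  stopifnot(inherits(acq, "acquisition_spec"))
  nx <- acq$matrix[1]; ny <- acq$matrix[2]; nf <- acq$n_frames
  npx <- nx * ny
  pix_list <- lapply(vessels, lumen_pixels, acq = acq)
  labels <- vapply(vessels, `[[`, "", "label")
  names(pix_list) <- labels

  for (k in seq_along(vessels)) {
    if (length(pix_list[[k]]) == 0L)
      stop(sprintf("vessel %s rasterizes to an empty pixel set", labels[k]))
    ij <- arrayInd(pix_list[[k]], c(nx, ny))
    if (any(ij[, 1] %in% c(1L, nx)) || any(ij[, 2] %in% c(1L, ny)))
      stop(sprintf("vessel %s does not fit inside the matrix", labels[k]))
  }
  if (length(vessels) > 1L) {
    for (a in seq_len(length(vessels) - 1L)) {
      for (b in seq(a + 1L, length(vessels))) {
        if (length(intersect(pix_list[[a]], pix_list[[b]])) > 0L)
          stop(sprintf("overlapping lumens: %s and %s", labels[a], labels[b]))
      }
    }
  }

  set.seed(acq$seed)
  vel <- if (acq$noise_sigma > 0) {
    matrix(stats::rnorm(npx * nf, sd = acq$noise_sigma), npx, nf)
  } else matrix(0, npx, nf)
  mag <- matrix(0.05, npx, nf)

  pixel_area <- acq$pixel_spacing^2
  curves <- matrix(NA_real_, nf, length(vessels),
                   dimnames = list(NULL, labels))
  areas <- numeric(length(vessels)); names(areas) <- labels

  for (k in seq_along(vessels)) {
    vs <- vessels[[k]]
    px <- pix_list[[k]]
    area <- length(px) * pixel_area
    q <- sample_waveform(vs$waveform, nf, acq$cardiac_period)  # ml/min
    v <- q / (area * 0.6)                                      # cm/s
    vel[px, ] <- vel[px, ] + rep(vs$direction_sign * v, each = length(px))
    mag[px, ] <- 1
    if (partial_volume) {
      ring <- setdiff(rim_pixels(vs, acq), unlist(pix_list))
      if (length(ring)) {
        vel[ring, ] <- vel[ring, ] + rep(0.5 * vs$direction_sign * v,
                                         each = length(ring))
        mag[ring, ] <- pmax(mag[ring, ], 0.5)
      }
    }
    curves[, k] <- q
    areas[k] <- area
  }

  vel <- apply_phase_wrap(vel, acq$venc)
  stack <- cine_stack(array(vel, c(nx, ny, nf)), array(mag, c(nx, ny, nf)),
                      venc = acq$venc, cardiac_period = acq$cardiac_period,
                      pixel_spacing = acq$pixel_spacing,
                      slice_thickness = acq$slice_thickness,
                      plane_label = plane_label)
  rois <- lapply(seq_along(vessels), function(k)
    roi_mask(labels[k], pix_list[[k]], vessels[[k]]$direction_sign, c(nx, ny)))
  names(rois) <- labels

  truth <- list(
    curves = curves, areas = areas,
    cardiac_period = acq$cardiac_period,
    metrics = data.frame(
      label = labels,
      area_mm2 = unname(areas),
      mean_flow = unname(colMeans(curves)),
      pi = vapply(seq_along(vessels), function(k) {
        m <- mean(curves[, k])
        if (m == 0) NA_real_ else (max(curves[, k]) - min(curves[, k])) / m
      }, numeric(1)),
      row.names = NULL
    )
  )
  class(truth) <- "ground_truth"
  list(stack = stack, rois = rois, truth = truth)
}
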