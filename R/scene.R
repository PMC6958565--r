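#' Vessel and CSF-channel labels known to the simulator
#' @export
VESSEL_LABELS <- c("ICA_L", "ICA_R", "VA_L", "VA_R", "BA",
                   "IJV_L", "IJV_R", "SSS", "StrS",
                   "AQUEDUCT", "C2C3_SAS")

#' Acquisition plane labels
#' @export
PLANE_LABELS <- c("extracranial_vessels", "intracranial_vessels",
                  "aqueduct", "c2c3")

#' Specify one vessel (or CSF channel) in an acquisition plane
#'
#' Geometry is a circular lumen: `center` in mm relative to the image centre,
#' `lumen_area` in mm^2. `direction_sign` uses the cranio-caudal-positive
#' convention: +1 for flow towards the feet (veins, systolic CSF flush),
#' -1 for flow towards the head (arteries). The stored phase image carries
#' the signed velocity; quantification re-applies the sign so that all
#' reported flow curves are positive in the vessel's own flow direction.
#'
#' @param label one of [VESSEL_LABELS].
#' @param center numeric length-2, lumen centre in mm from the image centre.
#' @param lumen_area lumen cross-section, mm^2; > 0.
#' @param direction_sign +1 (cranio-caudal) or -1 (caudo-cranial).
#' @param waveform a [waveform_spec()] for the vessel's volumetric flow.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(label, center, lumen_area, direction_sign, waveform) {
  label <- match.arg(label, VESSEL_LABELS)
  stopifnot(length(center) == 2L, is.numeric(center),
            inherits(waveform, "waveform_spec"))
  if (!is.finite(lumen_area) || lumen_area <= 0) stop("lumen_area must be > 0")
  if (!direction_sign %in% c(-1, 1)) stop("direction_sign must be +1 or -1")
  structure(list(label = label, center = as.numeric(center),
                 lumen_area = lumen_area, direction_sign = direction_sign,
                 waveform = waveform),
            class = "vessel_spec")
}

#' Specify a cardiac-gated acquisition
#'
#' Defaults follow a 2D cine phase-contrast protocol at 3T: 256 x 128 matrix,
#' 0.55 mm in-plane pixels, 5 mm slice, 32 frames per cardiac cycle, velocity
#' encoding 80 cm/s for blood planes (10 cm/s aqueduct, 5 cm/s cervical CSF).
#' `noise_sigma` is the standard deviation of additive Gaussian velocity
#' noise (a phase-noise proxy); if `NULL` it defaults to
#' `venc * 0.015 / pi` cm/s, i.e. 0.015 rad of phase noise (about 0.4 cm/s
#' at venc 80) - a high-SNR acquisition, chosen so that the weakest venous
#' pulsations the cohort model produces stay above the waveform-correlation
#' admission threshold of the segmentation, consistent with flow software
#' whose volumetric measurements are repeatable to a few percent.
#'
#' @param venc velocity encoding limit, cm/s; > 0.
#' @param matrix integer length-2, image matrix (nx, ny).
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @param cardiac_period cardiac cycle duration, s. Values outside the
#'   physiological 45-100 BPM gate are allowed with a warning.
#' @param n_frames cardiac frames per cycle (>= 8).
#' @param noise_sigma velocity noise SD, cm/s, or `NULL` for the default.
#' @param seed integer seed for the noise stream.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(venc = 80, matrix = c(256L, 128L),
                             pixel_spacing = 0.55, slice_thickness = 5,
                             cardiac_period = 0.9, n_frames = 32L,
                             noise_sigma = NULL, seed = 1L) {
  if (!is.finite(venc) || venc <= 0) stop("venc must be > 0")
  n_frames <- as.integer(n_frames)
  if (n_frames < 8L) stop("n_frames must be >= 8")
  bpm <- 60 / cardiac_period
  if (!is.finite(bpm) || cardiac_period <= 0)
    stop("cardiac_period must be > 0")
  if (bpm < 45 || bpm > 100)
    warning(sprintf("heart rate %.1f BPM outside the 45-100 BPM physiological gate", bpm))
  if (is.null(noise_sigma)) noise_sigma <- venc * 0.015 / pi
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(venc = venc, matrix = as.integer(matrix),
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 cardiac_period = cardiac_period, n_frames = n_frames,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "acquisition_spec")
}

# Pixel indices (in the nx x ny grid) whose centres fall inside the lumen
# disk. Pixel (i, j) has its centre at ((i - (nx+1)/2), (j - (ny+1)/2)) *
# pixel_spacing mm from the image centre.
lumen_pixels <- function(vessel, acq) {
  nx <- acq$matrix[1]; ny <- acq$matrix[2]
  cx <- (seq_len(nx) - (nx + 1) / 2) * acq$pixel_spacing
  cy <- (seq_len(ny) - (ny + 1) / 2) * acq$pixel_spacing
  r <- sqrt(vessel$lumen_area / pi)
  dx <- cx - vessel$center[1]
  dy <- cy - vessel$center[2]
  d2 <- outer(dx^2, dy^2, "+")
  which(d2 <= r^2)
}

# Ring of pixels just outside the lumen boundary (centre within one pixel
# spacing beyond the radius); used by the optional partial-volume model.
rim_pixels <- function(vessel, acq) {
  nx <- acq$matrix[1]; ny <- acq$matrix[2]
  cx <- (seq_len(nx) - (nx + 1) / 2) * acq$pixel_spacing
  cy <- (seq_len(ny) - (ny + 1) / 2) * acq$pixel_spacing
  r <- sqrt(vessel$lumen_area / pi)
  d2 <- outer((cx - vessel$center[1])^2, (cy - vessel$center[2])^2, "+")
  which(d2 > r^2 & d2 <= (r + acq$pixel_spacing)^2)
}
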