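# Names of the per-subject derived metrics, in reporting order.
METRIC_NAMES <- c("extra_acbf", "intra_acbf", "extra_vcbf", "intra_vcbf",
                  "alpha_extra", "alpha_intra",
                  "extra_blood_sv", "intra_blood_sv",
                  "spinal_csf_sv", "aqueductal_csf_sv",
                  "extra_arterial_pi", "intra_arterial_pi",
                  "extra_venous_pi", "intra_venous_pi",
                  "heart_rate")

#' Derive the full per-subject metric set from plane flow curves
#'
#' Takes the per-vessel flow curves of the four acquisition planes and
#' produces every derived quantity of the analysis: composite mean flows,
#' alpha venous corrections, blood stroke volumes (from the arteriovenous
#' flow), CSF stroke volumes, and one pulsatility index per arterial and per
#' venous tree (computed on the composite curves) at each level, plus heart
#' rate. Missing planes yield `NA` for the affected metrics and are listed
#' in the `missing_planes` attribute.
#'
#' @param plane_curves list with (any of) components `extracranial` and
#'   `intracranial` (named lists of per-vessel [flow_curve()]s), `aqueduct`
#'   and `c2c3` (single CSF [flow_curve()]s).
#' @return One-row `data.frame` of metrics (see `cranioflow:::METRIC_NAMES`),
#'   with attribute `missing_planes`.
#' @export
subject_metrics <- function(plane_curves) {
  out <- as.list(stats::setNames(rep(NA_real_, length(METRIC_NAMES)), METRIC_NAMES))
  missing_planes <- character(0)
  period <- NA_real_

  for (level in c("extra", "intra")) {
    plane <- paste0(if (level == "extra") "extracranial" else "intracranial")
    pc <- plane_curves[[plane]]
    if (is.null(pc)) { missing_planes <- c(missing_planes, plane); next }
    comp <- compose_flows(pc, level)
    period <- comp$arterial$cardiac_period
    ac <- alpha_correction(comp$arterial, comp$venous)
    av <- arteriovenous_flow(comp$arterial, ac$theoretical_vcbf)
    out[[paste0(level, "_acbf")]] <- mean(comp$arterial$samples)
    out[[paste0(level, "_vcbf")]] <- mean(comp$venous$samples)
    out[[paste0("alpha_", level)]] <- ac$alpha
    out[[paste0(level, "_blood_sv")]] <- blood_stroke_volume(av)
    out[[paste0(level, "_arterial_pi")]] <- pulsatility_index(comp$arterial)
    out[[paste0(level, "_venous_pi")]] <- pulsatility_index(comp$venous)
  }

  if (!is.null(plane_curves$c2c3)) {
    out$spinal_csf_sv <- as.numeric(csf_stroke_volume(plane_curves$c2c3))
    period <- plane_curves$c2c3$cardiac_period
  } else missing_planes <- c(missing_planes, "c2c3")

  if (!is.null(plane_curves$aqueduct)) {
    out$aqueductal_csf_sv <- as.numeric(csf_stroke_volume(plane_curves$aqueduct))
    period <- plane_curves$aqueduct$cardiac_period
  } else missing_planes <- c(missing_planes, "aqueduct")

  if (is.finite(period)) out$heart_rate <- 60 / period
  df <- as.data.frame(out)
  attr(df, "missing_planes") <- missing_planes
  df
}

#' Quantify one acquisition plane: segmentation to per-vessel flow curves
#'
#' For each listed vessel: a provisional magnitude-based lumen mask is
#' flood-filled around the seed, aliasing is detected on it (and the
#' acquisition rejected if more than half the pixels alias in any frame),
#' flagged pixels are de-aliased, the lumen is segmented by
#' waveform-correlation region growing, and the ROI mean-velocity curve is
#' converted to a flow curve.
#'
#' When the flow-based growth under-segments - recovering less than 98% of
#' the magnitude-mask area, as happens when a venous tree's pulsatile
#' component sits at or below the noise floor - the provisional magnitude
#' mask is used instead, emulating the operator's contour correction in
#' semi-automated practice. The fallback only triggers when the magnitude
#' mask itself is a plausible lumen (at least 3 pixels and under 10% of the
#' image) and is recorded in the returned log.
#'
#' @param stack a [cine_stack()].
#' @param seeds named list: vessel label -> list(seed = c(i, j),
#'   direction_sign = +1/-1).
#' @param params list of processing parameters: `aliasing_threshold`,
#'   `r_min`, `pulsatility_floor` (NULL = automatic), `smooth`.
#' @return Named list of [flow_curve()]s (positive in each vessel's flow
#'   direction), with per-vessel ROI areas in attribute `areas` and the
#'   aliasing/fallback log in attribute `log`.
#' @export
quantify_plane <- function(stack, seeds,
                           params = list(aliasing_threshold = 0.75,
                                         r_min = 0.7,
                                         pulsatility_floor = NULL)) {
  curves <- list()
  areas <- numeric(0)
  logs <- list()
  npx <- prod(dim(stack$velocity)[1:2])
  for (lab in names(seeds)) {
    sd_info <- seeds[[lab]]
    prov <- magnitude_roi(stack, sd_info$seed)
    prov_roi <- roi_mask(lab, prov, sd_info$direction_sign,
                         dim(stack$velocity)[1:2])
    det <- detect_aliasing(stack, prov_roi,
                           params$aliasing_threshold %||% 0.75)
    st <- dealias_roi(stack, prov_roi, params$aliasing_threshold %||% 0.75)
    prov_plausible <- length(prov) >= 3L && length(prov) <= 0.1 * npx
    roi <- tryCatch(
      segment_roi(st, sd_info$seed, lab, sd_info$direction_sign,
                  r_min = params$r_min %||% 0.7,
                  pulsatility_floor = params$pulsatility_floor,
                  smooth = params$smooth %||% 5L),
      error = function(e) e)
    fallback <- FALSE
    if (inherits(roi, "error")) {
      if (grepl("no pulsatile signal", conditionMessage(roi)) && prov_plausible) {
        roi <- prov_roi; fallback <- TRUE
      } else stop(roi)
    } else if (length(roi$pixels) < 0.98 * length(prov) && prov_plausible) {
      roi <- prov_roi; fallback <- TRUE
    }
    logs[[lab]] <- list(max_aliased_fraction = max(det$fraction),
                        reject = det$reject,
                        magnitude_fallback = fallback)
    mv <- mean_velocity_curve(st, roi)
    curves[[lab]] <- flow_curve(mv$velocity, mv$area, st$cardiac_period, lab)
    areas[lab] <- mv$area
  }
  attr(curves, "areas") <- areas
  attr(curves, "log") <- logs
  curves
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify a whole synthetic subject
#'
#' Rasterizes (or takes pre-rasterized) cine stacks for the four acquisition
#' planes of one subject scene and runs [quantify_plane()] plus
#' [subject_metrics()]. A plane whose aliasing detector rejects the
#' acquisition (> 50% of ROI pixels aliased in some frame) is re-acquired
#' at doubled venc - the protocol's rule - up to `max_venc_doublings`
#' times; this is only possible when the scene is available for
#' re-rasterization. A plane that still fails yields a partial record
#' (`NA` metrics for that plane) with a warning.
#'
#' @param scene one subject scene from [make_cohort()].
#' @param params processing parameters, as in [quantify_plane()].
#' @param stacks optional named list of pre-built [cine_stack()]s (e.g. read
#'   back from disk); when `NULL` the scene is rasterized in memory.
#' @param max_venc_doublings re-acquisition budget per plane (default 2).
#' @return One-row metrics `data.frame` as from [subject_metrics()].
#' @export
quantify_subject <- function(scene, params = list(), stacks = NULL,
                             max_venc_doublings = 2L) {
  plane_curves <- list()
  for (plane in names(scene$planes)) {
    pl <- scene$planes[[plane]]
    seeds <- lapply(pl$vessels, function(v) {
      nx <- pl$acq$matrix[1]; ny <- pl$acq$matrix[2]
      i <- round(v$center[1] / pl$acq$pixel_spacing + (nx + 1) / 2)
      j <- round(v$center[2] / pl$acq$pixel_spacing + (ny + 1) / 2)
      list(seed = c(i, j), direction_sign = v$direction_sign)
    })
    names(seeds) <- vapply(pl$vessels, `[[`, "", "label")

    curves <- NULL
    acq <- pl$acq
    for (attempt in 0:max_venc_doublings) {
      stack <- if (!is.null(stacks) && attempt == 0L) stacks[[plane]] else
        rasterize_cine(pl$vessels, acq, plane_label = plane)$stack
      res <- tryCatch(quantify_plane(stack, seeds, params),
                      error = function(e) e)
      if (!inherits(res, "error")) { curves <- res; break }
      rejected <- grepl("re-acquire", conditionMessage(res))
      can_retry <- rejected && attempt < max_venc_doublings &&
        (is.null(stacks) || attempt > 0L || !is.null(scene$planes))
      if (!can_retry) {
        warning(sprintf("%s plane %s: %s", scene$id %||% "subject", plane,
                        conditionMessage(res)))
        break
      }
      # protocol rule: repeat the acquisition with double venc (phase noise
      # is constant in radians, so velocity noise doubles with venc)
      acq$venc <- acq$venc * 2
      acq$noise_sigma <- acq$noise_sigma * 2
    }
    if (is.null(curves)) next
    if (plane %in% c("aqueduct", "c2c3")) {
      plane_curves[[plane]] <- curves[[1]]
    } else {
      key <- if (plane == "extracranial_vessels") "extracranial" else "intracranial"
      plane_curves[[key]] <- curves
    }
  }
  subject_metrics(plane_curves)
}
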