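#' Wrap a true velocity into the encoded range
#'
#' Phase-contrast velocity encoding stores velocity modulo `2 * venc`: any
#' component beyond +/- venc aliases into the opposite extreme of the range.
#' The stored value lies in `(-venc, +venc]` and equals the true velocity
#' whenever `|v| <= venc`.
#'
#' @param true_velocity numeric vector, cm/s.
#' @param venc velocity encoding limit, cm/s; > 0.
#' @return Stored (possibly aliased) velocity, cm/s, in `(-venc, +venc]`.
#' @examples
#' apply_phase_wrap(90, 80)   # -70
#' apply_phase_wrap(-90, 80)  # +70
#' @export
apply_phase_wrap <- function(true_velocity, venc) {
  if (!is.finite(venc) || venc <= 0) stop("venc must be > 0")
  w <- (true_velocity + venc) %% (2 * venc)
  w[w == 0] <- 2 * venc
  w - venc
}

#' Undo a single velocity wrap
#'
#' Recovers the true velocity of an aliased pixel under the single-wrap
#' assumption (`venc < |v_true| < 2*venc`): the corrected value is
#' `(2*venc - |v_error|)` with the sign opposite to the stored one. Zero
#' stored velocities are undefined under this rule and are returned
#' unchanged with a warning.
#'
#' @param v_error stored (aliased) velocity, cm/s; vectorised.
#' @param venc velocity encoding limit, cm/s.
#' @return Corrected velocity, cm/s; magnitude in `(venc, 2*venc)`.
#' @examples
#' correct_aliasing(-70, 80)  # +90
#' correct_aliasing(-4, 5)    # +6
#' @export
correct_aliasing <- function(v_error, venc) {
  if (!is.finite(venc) || venc <= 0) stop("venc must be > 0")
  out <- v_error
  zero <- v_error == 0
  if (any(zero)) {
    warning("zero stored velocity cannot be de-aliased; left unchanged")
  }
  idx <- !zero
  out[idx] <- (2 * venc - abs(v_error[idx])) * (-sign(v_error[idx]))
  out
}

#' Flag aliased pixels in a region of interest
#'
#' A pixel-frame is flagged as aliased when its stored velocity opposes the
#' vessel's flow direction *and* its magnitude exceeds
#' `aliasing_threshold * venc`. Acquisitions where more than half of the ROI
#' pixels alias in any frame cannot be corrected reliably and are flagged
#' for re-acquisition at doubled venc.
#'
#' @param stack a [cine_stack()].
#' @param roi a [roi_mask()].
#' @param aliasing_threshold magnitude gate as a fraction of venc (default 0.75).
#' @return List with `fraction` (aliased fraction per frame), `flagged`
#'   (n_pixels x n_frames logical matrix, rows in `roi$pixels` order) and
#'   `reject` (TRUE when any frame's fraction exceeds 0.5).
#' @export
detect_aliasing <- function(stack, roi, aliasing_threshold = 0.75) {
  stopifnot(inherits(stack, "cine_stack"), inherits(roi, "roi_mask"))
  if (length(roi$pixels) == 0L) stop("empty ROI")
  v <- roi_velocity_matrix(stack, roi)     # n_pixels x n_frames, stored sign
  opposed <- sign(v) == -roi$direction_sign
  flagged <- opposed & abs(v) > aliasing_threshold * stack$venc
  fraction <- colMeans(flagged)
  list(fraction = fraction, flagged = flagged, reject = any(fraction > 0.5))
}

#' De-alias a region of interest in place
#'
#' Applies [correct_aliasing()] to every pixel-frame flagged by
#' [detect_aliasing()]. Errors when the detector rejects the acquisition
#' (aliased fraction > 50% in some frame), unless `force = TRUE`.
#'
#' @inheritParams detect_aliasing
#' @param force correct anyway even if the acquisition is rejected.
#' @return The stack with corrected velocities inside the ROI.
#' @export
dealias_roi <- function(stack, roi, aliasing_threshold = 0.75, force = FALSE) {
  det <- detect_aliasing(stack, roi, aliasing_threshold)
  if (det$reject && !force)
    stop(sprintf("ROI %s: aliasing exceeds 50%% of pixels (max fraction %.2f); re-acquire with doubled venc",
                 roi$label, max(det$fraction)))
  if (!any(det$flagged)) return(stack)
  nf <- stack$n_frames
  for (t in seq_len(nf)) {
    hit <- det$flagged[, t]
    if (!any(hit)) next
    px <- roi$pixels[hit]
    frame <- stack$velocity[, , t]
    frame[px] <- correct_aliasing(frame[px], stack$venc)
    stack$velocity[, , t] <- frame
  }
  stack
}
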