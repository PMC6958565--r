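#' Build a volumetric flow curve from a mean-velocity waveform
#'
#' Flow in ml/min is velocity (cm/s) times ROI area (mm^2) times 0.6
#' (1 cm/s x 1 mm^2 = 10 mm^3/s = 0.01 ml/s = 0.6 ml/min).
#'
#' @param mean_velocity per-frame mean velocity, cm/s.
#' @param area ROI area, mm^2; > 0.
#' @param cardiac_period cycle duration, s.
#' @param label curve label.
#' @return An object of class `flow_curve`: list with `samples` (ml/min),
#'   `cardiac_period` (s) and `label`.
#' @examples
#' fc <- flow_curve(rep(10, 32), 25, 0.9)  # constant 150 ml/min
#' @export
flow_curve <- function(mean_velocity, area, cardiac_period, label = "flow") {
  if (!is.finite(area) || area <= 0) stop("area must be > 0")
  if (cardiac_period <= 0) stop("cardiac_period must be > 0")
  if (!all(is.finite(mean_velocity))) stop("non-finite velocities")
  structure(list(samples = mean_velocity * area * 0.6,
                 cardiac_period = cardiac_period, label = label),
            class = "flow_curve")
}

# Wrap raw samples (already ml/min) into a flow_curve.
as_flow_curve <- function(samples, cardiac_period, label = "flow") {
  stopifnot(all(is.finite(samples)), cardiac_period > 0)
  structure(list(samples = as.numeric(samples),
                 cardiac_period = cardiac_period, label = label),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %s: %d samples, period %.3f s, mean %.1f ml/min\n",
              x$label, length(x$samples), x$cardiac_period, mean(x$samples)))
  invisible(x)
}

# The vessel sets feeding each composite flow.
COMPOSITE_VESSELS <- list(
  extra_arterial = c("ICA_L", "ICA_R", "VA_L", "VA_R"),
  intra_arterial = c("ICA_L", "ICA_R", "BA"),
  extra_venous   = c("IJV_L", "IJV_R"),
  intra_venous   = c("SSS", "StrS")
)

#' Sum per-vessel flow curves into arterial and venous composites
#'
#' Extracranial arterial flow (ExtraACBF) sums both internal carotid and
#' both vertebral arteries; intracranial arterial flow (IntraACBF) sums both
#' carotids and the basilar artery. Measured venous flow sums both jugulars
#' (extracranial) or the sagittal plus straight sinus (intracranial).
#'
#' @param curves named list of [flow_curve()], names = vessel labels.
#' @param level `"extra"` or `"intra"`.
#' @return List with `arterial` and `venous` composite [flow_curve()]s.
#' @export
compose_flows <- function(curves, level = c("extra", "intra")) {
  level <- match.arg(level)
  art_set <- COMPOSITE_VESSELS[[paste0(level, "_arterial")]]
  ven_set <- COMPOSITE_VESSELS[[paste0(level, "_venous")]]
  missing <- setdiff(c(art_set, ven_set), names(curves))
  if (length(missing))
    stop(sprintf("missing vessel flow curve(s): %s", paste(missing, collapse = ", ")))
  sum_set <- function(set, label) {
    period <- curves[[set[1]]]$cardiac_period
    n <- length(curves[[set[1]]]$samples)
    s <- rep(0, n)
    for (lab in set) {
      cv <- curves[[lab]]
      if (length(cv$samples) != n || !isTRUE(all.equal(cv$cardiac_period, period)))
        stop(sprintf("curve %s has mismatched sampling", lab))
      s <- s + cv$samples
    }
    as_flow_curve(s, period, label)
  }
  list(arterial = sum_set(art_set, sprintf("%s_ACBF", level)),
       venous   = sum_set(ven_set, sprintf("%s_VCBF", level)))
}

#' Alpha venous correction
#'
#' Measured venous drainage misses peripheral veins; under flow balance the
#' cycle-mean arterial inflow must equal the cycle-mean theoretical venous
#' outflow. The correction factor is `alpha = mean(ACBF) / mean(VCBF)` and
#' the theoretical venous flow is `alpha x` the measured one, pointwise.
#'
#' @param acbf arterial composite [flow_curve()].
#' @param vcbf_measured measured venous composite [flow_curve()].
#' @return List with `alpha` and `theoretical_vcbf` (a [flow_curve()] whose
#'   mean equals `mean(acbf)` to floating point).
#' @export
alpha_correction <- function(acbf, vcbf_measured) {
  mv <- mean(vcbf_measured$samples)
  if (!is.finite(mv) || mv <= 0) stop("non-positive mean venous flow")
  alpha <- mean(acbf$samples) / mv
  theo <- as_flow_curve(alpha * vcbf_measured$samples,
                        vcbf_measured$cardiac_period,
                        paste0(vcbf_measured$label, "_theoretical"))
  list(alpha = alpha, theoretical_vcbf = theo)
}

#' Arteriovenous flow
#'
#' Pointwise difference between arterial inflow and theoretical venous
#' outflow; by construction of the alpha correction its cycle mean is zero
#' to floating point.
#'
#' @param acbf arterial composite [flow_curve()].
#' @param theoretical_vcbf alpha-corrected venous [flow_curve()].
#' @return A [flow_curve()] of the arteriovenous flow.
#' @export
arteriovenous_flow <- function(acbf, theoretical_vcbf) {
  if (length(acbf$samples) != length(theoretical_vcbf$samples) ||
      !isTRUE(all.equal(acbf$cardiac_period, theoretical_vcbf$cardiac_period)))
    stop("mismatched sampling between arterial and venous curves")
  as_flow_curve(acbf$samples - theoretical_vcbf$samples,
                acbf$cardiac_period, "arteriovenous")
}

# Cyclic cumulative trapezoidal integral of a flow curve. Input ml/min;
# returns the volume trace V(t) in ml at the n sample times plus the closure
# point (sample n wraps to sample 1), so length n + 1 and V[1] = 0.
cyclic_volume_trace <- function(curve) {
  q <- curve$samples / 60                      # ml/s
  n <- length(q)
  dt <- curve$cardiac_period / n
  qc <- c(q, q[1])
  c(0, cumsum((qc[-1] + qc[-(n + 1)]) / 2 * dt))
}

#' Blood stroke volume
#'
#' Cyclic trapezoidal integration of the arteriovenous flow gives the
#' cerebral blood volume change V(t) over the cycle; the stroke volume is
#' its range `max(V) - min(V)` in ml per cardiac cycle. Warns when the input
#' curve's cycle mean exceeds 1% of its peak (the alpha correction should
#' have balanced it).
#'
#' @param av_flow arteriovenous [flow_curve()].
#' @return Stroke volume, ml per cardiac cycle.
#' @export
blood_stroke_volume <- function(av_flow) {
  m <- mean(av_flow$samples)
  pk <- max(abs(av_flow$samples))
  if (pk > 0 && abs(m) > 0.01 * pk)
    warning(sprintf("arteriovenous flow has non-zero cycle mean (%.3g ml/min)", m))
  v <- cyclic_volume_trace(av_flow)
  max(v) - min(v)
}

#' CSF stroke volume
#'
#' The volume of CSF displaced in each direction during the cycle: the mean
#' of the areas under the positive and (absolute) negative lobes of the
#' signed flow curve, by trapezoidal integration with periodic closure.
#' Oscillatory (bidirectional) flow is assumed; a curve that never changes
#' sign is still integrated but flagged.
#'
#' @param csf_flow signed CSF [flow_curve()] (ml/min).
#' @return Stroke volume, ml per cardiac cycle, with attribute
#'   `"unidirectional"` set to TRUE when the curve has no zero crossing.
#' @export
csf_stroke_volume <- function(csf_flow) {
  q <- csf_flow$samples / 60                   # ml/s
  n <- length(q)
  dt <- csf_flow$cardiac_period / n
  qc <- c(q, q[1])
  tc <- (0:n) * dt
  pos <- pracma::trapz(tc, pmax(qc, 0))
  neg <- pracma::trapz(tc, pmax(-qc, 0))
  unidir <- all(q >= 0) || all(q <= 0)
  if (unidir)
    warning(sprintf("CSF curve %s is unidirectional; oscillatory flow expected",
                    csf_flow$label))
  structure((pos + neg) / 2, unidirectional = unidir)
}

#' Pulsatility index
#'
#' Gosling's index on the raw cine samples (no interpolation):
#' `PI = (max - min) / mean`.
#'
#' @param curve a [flow_curve()] with non-zero mean.
#' @return Dimensionless PI.
#' @export
pulsatility_index <- function(curve) {
  m <- mean(curve$samples)
  if (m == 0) stop("pulsatility index undefined for zero-mean curve")
  (max(curve$samples) - min(curve$samples)) / m
}
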