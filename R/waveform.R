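#' Specify a periodic volumetric flow waveform
#'
#' A `waveform_spec` describes one vessel's (or CSF channel's) volumetric flow
#' over the cardiac cycle in closed form. Two shapes are supported:
#' `"sinusoid"` (used wherever a closed-form oracle is wanted: mean `M`,
#' half-range `A`, so the pulsatility index is exactly `2A/M`) and
#' `"gamma"`, a gamma-variate systolic pulse riding on a diastolic baseline,
#' the usual phenomenological model for arterial waveforms.
#'
#' For both shapes the sampled curve is re-centred so its cycle mean equals
#' `mean_flow` exactly, and scaled so its peak-to-trough range equals
#' `2 * pulse_amplitude`. `systolic_fraction` places the systolic peak (as a
#' fraction of the cycle) and only matters for the gamma shape;
#' `phase_offset` rotates the whole waveform.
#'
#' @param mean_flow cycle-mean volumetric flow, ml/min (may be 0 or negative
#'   for CSF channels).
#' @param pulse_amplitude half of the peak-to-trough flow range, ml/min; >= 0.
#' @param systolic_fraction peak position as a fraction of the cycle, in (0,1).
#' @param phase_offset cyclic shift as a fraction of the cycle, in [0,1).
#' @param shape `"sinusoid"`, `"gamma"`, or `"harmonics"` (a truncated
#'   Fourier series with explicit coefficients; used by the cohort
#'   simulator to give venous waveforms second-harmonic freedom).
#' @param harmonics for `shape = "harmonics"`: list with `amp` (ml/min,
#'   one amplitude per harmonic 1, 2, ...) and `phase` (per-harmonic cyclic
#'   shift as a fraction of the cycle). `pulse_amplitude` and
#'   `systolic_fraction` are ignored for this shape; the sampled range is
#'   whatever the coefficients imply.
#' @return An object of class `waveform_spec`.
#' @examples
#' w <- waveform_spec(600, 300)
#' q <- sample_waveform(w, 32, 0.9)
#' mean(q)  # 600
#' @export
waveform_spec <- function(mean_flow, pulse_amplitude,
                          systolic_fraction = 0.3, phase_offset = 0,
                          shape = c("sinusoid", "gamma", "harmonics"),
                          harmonics = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(mean_flow), length(mean_flow) == 1L, is.finite(mean_flow))
  if (!is.finite(pulse_amplitude) || pulse_amplitude < 0)
    stop("pulse_amplitude must be >= 0")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must lie in (0, 1)")
  if (phase_offset < 0 || phase_offset >= 1)
    stop("phase_offset must lie in [0, 1)")
  if (shape == "harmonics") {
    if (is.null(harmonics) || !all(c("amp", "phase") %in% names(harmonics)) ||
        length(harmonics$amp) != length(harmonics$phase))
      stop("shape 'harmonics' needs harmonics = list(amp, phase) of equal length")
  }
  structure(list(mean_flow = mean_flow,
                 pulse_amplitude = pulse_amplitude,
                 systolic_fraction = systolic_fraction,
                 phase_offset = phase_offset,
                 shape = shape,
                 harmonics = harmonics),
            class = "waveform_spec")
}

# Unit-less gamma-variate pulse, peak 1 at x = tau; x is cycle fraction in [0,1).
gamma_pulse <- function(x, tau, power = 3) {
  x <- x %% 1
  (x / tau)^power * exp(power * (1 - x / tau))
}

#' Sample a flow waveform over one cardiac cycle
#'
#' Evaluates the waveform at `n_frames` equally spaced time points
#' `t_k = (k-1)/n_frames * cardiac_period`, the gating convention of a
#' retrospectively gated cine (frame 1 at the cardiac trigger). The sampled
#' curve is normalised so that its arithmetic mean equals `spec$mean_flow`
#' and its range equals `2 * spec$pulse_amplitude` exactly.
#'
#' @param spec a [waveform_spec()].
#' @param n_frames number of cardiac frames (>= 8; acquisitions use 32).
#' @param cardiac_period cycle duration in seconds; must be > 0.
#' @return Numeric vector of `n_frames` flows in ml/min.
#' @export
sample_waveform <- function(spec, n_frames = 32L, cardiac_period = 0.9) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (!is.finite(cardiac_period) || cardiac_period <= 0)
    stop("cardiac_period must be a positive duration in seconds")
  n_frames <- as.integer(n_frames)
  if (n_frames < 8L) stop("n_frames must be >= 8")
  x <- (seq_len(n_frames) - 1L) / n_frames - spec$phase_offset
  if (spec$shape == "harmonics") {
    base <- rep(0, n_frames)
    for (k in seq_along(spec$harmonics$amp))
      base <- base + spec$harmonics$amp[k] *
        sin(2 * pi * k * (x - spec$harmonics$phase[k]))
    return(spec$mean_flow + base - mean(base))
  }
  base <- switch(spec$shape,
    sinusoid = sin(2 * pi * x),
    gamma    = gamma_pulse(x, spec$systolic_fraction)
  )
  if (spec$pulse_amplitude == 0) return(rep(spec$mean_flow, n_frames))
  rng <- max(base) - min(base)
  if (rng == 0) return(rep(spec$mean_flow, n_frames))
  shaped <- (base - mean(base)) * (2 * spec$pulse_amplitude / rng)
  spec$mean_flow + shaped
}
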