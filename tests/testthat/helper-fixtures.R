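# Shared fixtures: all synthetic, built in code.

# One-vessel scene on a small matrix; returns rasterization result.
single_vessel_scene <- function(mean_flow = 600, amplitude = 300,
                                area = 28, venc = 80, noise_sigma = 0,
                                seed = 1L, matrix = c(64L, 64L),
                                period = 0.9, shape = "sinusoid",
                                sign = -1) {
  w <- waveform_spec(mean_flow, amplitude, shape = shape)
  v <- vessel_spec("ICA_L", c(0, 0), area, sign, w)
  acq <- acquisition_spec(venc = venc, matrix = matrix,
                          cardiac_period = period,
                          noise_sigma = noise_sigma, seed = seed)
  rasterize_cine(list(v), acq)
}

# Segmentation + quantification of a single-vessel stack; returns the
# mean flow estimate (ml/min).
quantify_single_vessel <- function(ras, sign = -1) {
  curves <- quantify_plane(ras$stack,
                           list(ICA_L = list(seed = c(33L, 33L),
                                             direction_sign = sign)))
  mean(curves$ICA_L$samples)
}

# Fine-grid trapezoidal lobe integration oracle for CSF stroke volume:
# f takes time in seconds over [0, T], flow in ml/s.
csf_sv_oracle <- function(f, T, n = 1e5) {
  t <- seq(0, T, length.out = n + 1)
  q <- f(t)
  pos <- pracma::trapz(t, pmax(q, 0))
  neg <- pracma::trapz(t, pmax(-q, 0))
  (pos + neg) / 2
}

# Cohort metrics columns used across tests.
ALL_METRICS <- c("extra_acbf", "intra_acbf", "extra_vcbf", "intra_vcbf",
                 "alpha_extra", "alpha_intra", "extra_blood_sv",
                 "intra_blood_sv", "spinal_csf_sv", "aqueductal_csf_sv",
                 "extra_arterial_pi", "intra_arterial_pi",
                 "extra_venous_pi", "intra_venous_pi", "heart_rate")
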