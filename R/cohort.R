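#' Default cohort configuration
#'
#' Group-level parameter means and SDs for the two study groups (healthy
#' young volunteers, HYV, n = 16 in the reference design; healthy elderly
#' volunteers, HEV, n = 19): composite mean flows (ml/min), tree pulsatility
#' indices, blood and spinal CSF stroke volumes (ml per cardiac cycle), the
#' aqueductal-to-spinal stroke-volume ratio, and heart rate (beats/min).
#' Per-subject values are drawn from normal distributions with these
#' moments; negative draws of positive-by-definition quantities are redrawn.
#'
#' The geometry block fixes each acquisition plane's vessel layout (circular
#' lumens, centres in mm relative to the image centre, areas in mm^2) and
#' the fixed fractions by which each composite flow is split across its
#' vessels. Defaults use a 96 x 96 cropped field of view around the vessels
#' at the protocol's 0.55 mm pixels; velocity encodings are 80 cm/s for
#' blood planes, 10 cm/s at the aqueduct and 5 cm/s at C2-C3.
#'
#' @param matrix image matrix for all planes (integer length-1 or 2).
#' @param noise_sigma velocity noise SD in cm/s, or `NULL` to scale with
#'   each plane's venc (0.015 rad of phase noise).
#' @param arterial_shape waveform family for the arterial tree
#'   (gamma-variate systolic pulse by default). Venous waveforms are not a
#'   fixed family: each subject's venous composite is synthesized as a
#'   two-harmonic Fourier series whose range matches the drawn venous
#'   pulsatility and whose arteriovenous stroke volume matches the drawn
#'   blood SV (see `cranioflow:::solve_venous_waveform`); a single fixed
#'   venous shape cannot satisfy both constraints at the reference values.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(matrix = 96L, noise_sigma = NULL,
                          arterial_shape = c("gamma", "sinusoid")) {
  arterial_shape <- match.arg(arterial_shape)
  if (length(matrix) == 1L) matrix <- c(matrix, matrix)
  gp <- data.frame(
    param = c("extra_acbf", "intra_acbf", "extra_vcbf", "intra_vcbf",
              "extra_arterial_pi", "intra_arterial_pi",
              "extra_venous_pi", "intra_venous_pi",
              "extra_blood_sv", "intra_blood_sv",
              "spinal_csf_sv", "aqueduct_sv_ratio", "heart_rate"),
    HYV_mean = c(716, 670, 449, 478, 0.85, 0.77, 0.47, 0.25,
                 0.91, 0.76, 0.34, 0.1176, 69),
    HYV_sd   = c(129, 158, 173, 94, 0.17, 0.22, 0.25, 0.16,
                 0.39, 0.30, 0.21, 0.030, 14),
    HEV_mean = c(588, 593, 533, 379, 1.31, 1.16, 0.86, 0.52,
                 0.98, 1.08, 0.51, 0.0980, 70),
    HEV_sd   = c(119, 107, 161, 88, 0.32, 0.17, 0.40, 0.16,
                 0.32, 0.21, 0.20, 0.030, 11)
  )
  geometry <- list(
    extracranial_vessels = list(
      venc = 80,
      vessels = data.frame(
        label = c("ICA_L", "ICA_R", "VA_L", "VA_R", "IJV_L", "IJV_R"),
        cx = c(-9, 9, -4.5, 4.5, -16, 16),
        cy = c(7, 7, -7, -7, 0, 0),
        area = c(28, 28, 12, 12, 40, 40),
        sign = c(-1, -1, -1, -1, 1, 1),
        fraction = c(0.36, 0.36, 0.14, 0.14, 0.5, 0.5),
        tree = c("arterial", "arterial", "arterial", "arterial",
                 "venous", "venous"))),
    intracranial_vessels = list(
      venc = 80,
      vessels = data.frame(
        label = c("ICA_L", "ICA_R", "BA", "SSS", "StrS"),
        cx = c(-7, 7, 0, 0, 0),
        cy = c(2, 2, -5, 13, -13),
        area = c(24, 24, 14, 45, 18),
        sign = c(-1, -1, -1, 1, 1),
        fraction = c(0.42, 0.42, 0.16, 0.72, 0.28),
        tree = c("arterial", "arterial", "arterial", "venous", "venous"))),
    aqueduct = list(
      venc = 10,
      vessels = data.frame(label = "AQUEDUCT", cx = 0, cy = 0, area = 5,
                           sign = 1, fraction = 1, tree = "csf")),
    c2c3 = list(
      venc = 5,
      vessels = data.frame(label = "C2C3_SAS", cx = 0, cy = 0, area = 80,
                           sign = 1, fraction = 1, tree = "csf"))
  )
  structure(list(group_params = gp, geometry = geometry,
                 matrix = as.integer(matrix), pixel_spacing = 0.55,
                 slice_thickness = 5, n_frames = 32L,
                 noise_sigma = noise_sigma,
                 arterial_shape = arterial_shape,
                 arterial_systolic_fraction = 0.30,
                 venous_systolic_fraction = 0.40,
                 csf_phase = c(spinal = 0.05, aqueduct = 0.10),
                 max_redraws = 100L),
            class = "cohort_config")
}

# Draw from N(mean, sd) truncated to (lo, hi); redraw up to `cap` times.
draw_trunc <- function(mean, sd, lo = 0, hi = Inf, cap = 100L) {
  for (i in seq_len(cap)) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  stop(sprintf("could not draw a value in (%g, %g) from N(%g, %g) in %d tries",
               lo, hi, mean, sd, cap))
}

# Synthesize the venous composite's pulsatile part as a two-harmonic
# Fourier series P(x) = u sin(2 pi (x - d1)) + v sin(4 pi (x - d2)) whose
# range matches the drawn venous pulsatility (Rv = PI_v * Mv) and whose
# arteriovenous stroke volume (arterial curve qa minus alpha-scaled venous)
# matches the drawn blood SV target. A single-harmonic venous waveform
# cannot do both: its fundamental is pinned by the venous PI, which places
# a floor under the arteriovenous amplitude; the second harmonic decouples
# the two constraints. Multi-start Nelder-Mead on the relative residuals;
# the realized values (usually exact to <1e-3) are recorded in the truth.
solve_venous_waveform <- function(qa, Ma, Mv, Rv, sv_target, T, nf,
                                  n_harmonics = 3L) {
  x <- (seq_len(nf) - 1L) / nf
  alpha <- Ma / Mv
  K <- n_harmonics
  eval_theta <- function(th) {
    amp <- abs(th[1:K]); ph <- th[(K + 1):(2 * K)]
    P <- rep(0, nf)
    for (k in seq_len(K))
      P <- P + amp[k] * sin(2 * pi * k * (x - ph[k]))
    av <- as_flow_curve(qa - alpha * (Mv + P - mean(P)), T)
    sv <- suppressWarnings(blood_stroke_volume(av))
    rng <- max(P) - min(P)
    ((rng - Rv) / Rv)^2 + ((sv - sv_target) / sv_target)^2
  }
  best <- NULL
  for (d1 in c(0.02, 0.1, 0.25, 0.45, 0.7)) {
    th0 <- c(Rv / 2, Rv / 6, rep(Rv / 12, K - 2L),
             d1 + 0.05 * (seq_len(K) - 1L))
    opt <- stats::optim(th0, eval_theta, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$value < 1e-8) break
  }
  th <- best$par
  list(amp = abs(th[1:K]), phase = th[(K + 1):(2 * K)] %% 1,
       residual = best$value)
}

# Build the vessel_spec list + true composite curves for one subject.
build_subject_scene <- function(draws, config, noise_seeds) {
  T <- 60 / draws$heart_rate
  nf <- config$n_frames
  planes <- list()
  true_curves <- list()

  venous_fit <- list()
  for (level in c("extra", "intra")) {
    Ma <- draws[[paste0(level, "_acbf")]]
    Mv <- draws[[paste0(level, "_vcbf")]]
    pa <- draws[[paste0(level, "_arterial_pi")]]
    pv <- draws[[paste0(level, "_venous_pi")]]
    qa <- sample_waveform(
      waveform_spec(Ma, pa * Ma / 2, config$arterial_systolic_fraction,
                    0, config$arterial_shape), nf, T)
    venous_fit[[level]] <- solve_venous_waveform(
      qa, Ma, Mv, Rv = pv * Mv,
      sv_target = draws[[paste0(level, "_blood_sv")]], T = T, nf = nf)
  }

  for (plane in names(config$geometry)) {
    geo <- config$geometry[[plane]]
    level <- if (plane == "extracranial_vessels") "extra"
             else if (plane == "intracranial_vessels") "intra" else NULL
    vessels <- vector("list", nrow(geo$vessels))
    for (k in seq_len(nrow(geo$vessels))) {
      row <- geo$vessels[k, ]
      wf <- if (identical(row$tree, "arterial")) {
        M <- draws[[paste0(level, "_acbf")]] * row$fraction
        p <- draws[[paste0(level, "_arterial_pi")]]
        waveform_spec(M, p * M / 2, config$arterial_systolic_fraction, 0,
                      config$arterial_shape)
      } else if (identical(row$tree, "venous")) {
        M <- draws[[paste0(level, "_vcbf")]] * row$fraction
        p <- draws[[paste0(level, "_venous_pi")]]
        fit <- venous_fit[[level]]
        waveform_spec(M, p * M / 2, config$venous_systolic_fraction, 0,
                      shape = "harmonics",
                      harmonics = list(amp = row$fraction * fit$amp,
                                       phase = fit$phase))
      } else if (identical(row$label, "AQUEDUCT")) {
        sv <- draws$spinal_csf_sv * draws$aqueduct_sv_ratio
        waveform_spec(0, 60 * pi * sv / T, 0.3,
                      config$csf_phase[["aqueduct"]], "sinusoid")
      } else {
        waveform_spec(0, 60 * pi * draws$spinal_csf_sv / T, 0.3,
                      config$csf_phase[["spinal"]], "sinusoid")
      }
      vessels[[k]] <- vessel_spec(row$label, c(row$cx, row$cy), row$area,
                                  row$sign, wf)
    }
    acq <- acquisition_spec(venc = geo$venc, matrix = config$matrix,
                            pixel_spacing = config$pixel_spacing,
                            slice_thickness = config$slice_thickness,
                            cardiac_period = T, n_frames = nf,
                            noise_sigma = config$noise_sigma,
                            seed = noise_seeds[[plane]])
    planes[[plane]] <- list(vessels = vessels, acq = acq)
    true_curves[[plane]] <- lapply(vessels, function(v)
      as_flow_curve(sample_waveform(v$waveform, nf, T), T, v$label))
    names(true_curves[[plane]]) <- geo$vessels$label
  }
  list(planes = planes, true_curves = true_curves, cardiac_period = T)
}

# True metrics implied by a scene's waveforms (exact pipeline input).
scene_truth_metrics <- function(scene) {
  pc <- list(
    extracranial = scene$true_curves$extracranial_vessels,
    intracranial = scene$true_curves$intracranial_vessels,
    aqueduct = scene$true_curves$aqueduct[[1]],
    c2c3 = scene$true_curves$c2c3[[1]]
  )
  suppressWarnings(subject_metrics(pc))
}

#' Simulate a two-group cohort of synthetic subjects
#'
#' Draws per-subject hydro-hemodynamic parameters from the group-level
#' normal distributions in `config$group_params`, builds each subject's
#' four-plane vessel scene (waveforms, geometry, acquisition settings with
#' per-plane noise seeds), and records both the configured draws and the
#' exact ground-truth metrics implied by the generated waveforms. The
#' venous waveform's phase lag is solved per level so the arteriovenous
#' stroke volume matches the drawn target where the drawn pulsatilities
#' permit (clamped otherwise; the realized truth is what is recorded).
#'
#' @param n_young,n_elderly group sizes (>= 1).
#' @param seed integer; the whole cohort is reproducible under it.
#' @param config a [cohort_config()].
#' @return List of class `cohort`: `subjects` (list of scenes with `id`,
#'   `group`, `planes`), `truth` (per-subject ground-truth metrics,
#'   data.frame with `subject`, `group` + metric columns), `configured`
#'   (the drawn parameter targets) and `config`.
#' @export
make_cohort <- function(n_young, n_elderly, seed = 1L,
                        config = cohort_config()) {
  stopifnot(n_young >= 1, n_elderly >= 1)
  set.seed(as.integer(seed))
  gp <- config$group_params
  groups <- c(rep("HYV", n_young), rep("HEV", n_elderly))
  subjects <- vector("list", length(groups))
  truth <- NULL; configured <- NULL

  for (s in seq_along(groups)) {
    g <- groups[s]
    mu <- stats::setNames(gp[[paste0(g, "_mean")]], gp$param)
    sdv <- stats::setNames(gp[[paste0(g, "_sd")]], gp$param)
    draws <- list()
    for (p in gp$param) {
      draws[[p]] <- if (p == "heart_rate")
        draw_trunc(mu[[p]], sdv[[p]], 45, 100, config$max_redraws)
      else
        draw_trunc(mu[[p]], sdv[[p]], 0, Inf, config$max_redraws)
    }
    noise_seeds <- as.list(stats::setNames(
      sample.int(.Machine$integer.max - 1L, length(config$geometry)),
      names(config$geometry)))
    scene <- build_subject_scene(draws, config, noise_seeds)
    scene$id <- sprintf("%s_%02d", g, s)
    scene$group <- g
    subjects[[s]] <- scene
    tm <- scene_truth_metrics(scene)
    truth <- rbind(truth, cbind(data.frame(subject = scene$id, group = g), tm))
    configured <- rbind(configured,
                        cbind(data.frame(subject = scene$id, group = g),
                              as.data.frame(draws)))
  }
  structure(list(subjects = subjects, truth = truth,
                 configured = configured, config = config),
            class = "cohort")
}

#' Quantify every subject of a simulated cohort through the full pipeline
#'
#' Rasterizes each subject's four planes (with their stored noise seeds) and
#' runs segmentation + flow quantification, returning the cohort metrics
#' table that feeds the statistical layer.
#'
#' @param cohort a [make_cohort()] result.
#' @param params processing parameters, as in [quantify_plane()].
#' @return `data.frame` with `subject`, `group` and all metric columns.
#' @export
quantify_cohort <- function(cohort, params = list()) {
  out <- NULL
  for (scene in cohort$subjects) {
    m <- tryCatch(quantify_subject(scene, params),
                  error = function(e) {
                    warning(sprintf("subject %s: %s", scene$id, conditionMessage(e)))
                    subject_metrics(list())
                  })
    out <- rbind(out, cbind(data.frame(subject = scene$id, group = scene$group), m))
  }
  out
}
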