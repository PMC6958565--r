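#' Write a cine stack as NIfTI volumes with a JSON sidecar
#'
#' Velocity and magnitude series are written as 4D NIfTI files (4th axis =
#' cardiac frame) named `<prefix>_velocity.nii.gz` and
#' `<prefix>_magnitude.nii.gz`, with acquisition metadata in
#' `<prefix>.json` (`venc_cm_s`, `cardiac_period_s`, `pixel_spacing_mm`,
#' `slice_thickness_mm`, `plane_label`).
#'
#' @param stack a [cine_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The sidecar path, invisibly.
#' @export
write_cine <- function(stack, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(stack$velocity)
  to4d <- function(a) array(a, c(dims[1], dims[2], 1, dims[3]))
  pd <- c(stack$pixel_spacing, stack$pixel_spacing, stack$slice_thickness,
          stack$cardiac_period / stack$n_frames)
  RNifti::writeNifti(RNifti::asNifti(to4d(stack$velocity), pixdim = pd),
                     file.path(dir, paste0(prefix, "_velocity.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(to4d(stack$magnitude), pixdim = pd),
                     file.path(dir, paste0(prefix, "_magnitude.nii.gz")))
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(venc_cm_s = stack$venc,
                            cardiac_period_s = stack$cardiac_period,
                            pixel_spacing_mm = stack$pixel_spacing,
                            slice_thickness_mm = stack$slice_thickness,
                            plane_label = stack$plane_label),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a cine stack written by [write_cine()]
#'
#' @param dir directory holding the files.
#' @param prefix file-name prefix used at write time.
#' @param raw_phase set TRUE when the velocity volume stores raw phase in
#'   radians instead of cm/s; values are then converted via
#'   `v = venc * phase / pi`.
#' @return A [cine_stack()].
#' @export
read_cine <- function(dir, prefix, raw_phase = FALSE) {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  req <- c("venc_cm_s", "cardiac_period_s", "pixel_spacing_mm",
           "slice_thickness_mm", "plane_label")
  if (!all(req %in% names(meta)))
    stop(sprintf("sidecar %s.json is missing fields: %s", prefix,
                 paste(setdiff(req, names(meta)), collapse = ", ")))
  rd <- function(kind) {
    a <- RNifti::readNifti(file.path(dir, paste0(prefix, "_", kind, ".nii.gz")))
    d <- dim(a)
    array(as.numeric(a), c(d[1], d[2], d[length(d)]))
  }
  vel <- rd("velocity")
  if (raw_phase) vel <- meta$venc_cm_s * vel / pi
  cine_stack(vel, rd("magnitude"),
             venc = meta$venc_cm_s, cardiac_period = meta$cardiac_period_s,
             pixel_spacing = meta$pixel_spacing_mm,
             slice_thickness = meta$slice_thickness_mm,
             plane_label = meta$plane_label)
}

#' Write per-vessel ground-truth curves as CSV
#'
#' One row per vessel per cardiac frame: `label, frame, time_s,
#' flow_ml_min`, plus the rasterized areas in the attached metrics table
#' (written as `<prefix>_truth_metrics.csv`).
#'
#' @param truth a `ground_truth` from [rasterize_cine()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return The curves CSV path, invisibly.
#' @export
write_ground_truth <- function(truth, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- nrow(truth$curves)
  dt <- truth$cardiac_period / nf
  long <- do.call(rbind, lapply(colnames(truth$curves), function(lab)
    data.frame(label = lab, frame = seq_len(nf),
               time_s = (seq_len(nf) - 1) * dt,
               flow_ml_min = truth$curves[, lab])))
  path <- file.path(dir, paste0(prefix, "_truth_curves.csv"))
  utils::write.csv(long, path, row.names = FALSE)
  utils::write.csv(truth$metrics,
                   file.path(dir, paste0(prefix, "_truth_metrics.csv")),
                   row.names = FALSE)
  invisible(path)
}

#' Write measured flow curves as a long-format CSV
#'
#' One row per curve per cardiac frame: `label, frame, time_s,
#' flow_ml_min`.
#'
#' @param curves named list of [flow_curve()]s (e.g. from
#'   [quantify_plane()]).
#' @param path output CSV path.
#' @export
write_flow_curves <- function(curves, path) {
  long <- do.call(rbind, lapply(names(curves), function(lab) {
    cv <- curves[[lab]]
    n <- length(cv$samples)
    data.frame(label = lab, frame = seq_len(n),
               time_s = (seq_len(n) - 1) * cv$cardiac_period / n,
               flow_ml_min = cv$samples)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a ROI mask as integer-label NIfTI
#' @param roi a [roi_mask()].
#' @param path `.nii.gz` path.
#' @export
write_mask <- function(roi, path) {
  img <- array(0L, roi$dim)
  img[roi$pixels] <- 1L
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}

#' @rdname write_mask
#' @param label,direction_sign mask metadata (not stored in the NIfTI).
#' @export
read_mask <- function(path, label, direction_sign) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  roi_mask(label, which(img != 0), direction_sign, d[1:2])
}
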