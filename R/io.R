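# Export helpers: NIfTI volumes and JSON detection reports.

#' Write a 3D volume as NIfTI
#'
#' Voxel spacing is derived from the protocol geometry (`fov_mm / matrix`).
#' Requires the RNifti package.
#'
#' @param volume 3D array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param fov_mm Field of view (mm).
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(volume, path, fov_mm = 220) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export")
  }
  vox <- fov_mm / dim(volume)[1]
  img <- RNifti::asNifti(volume, pixdim = rep(vox, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialize a detection result as a JSON report
#'
#' Timepoints, intervals, per-beat statistics, retained synchronicity
#' regions and the configuration are written as a JSON object; windows and
#' masks are summarized, not dumped.
#'
#' @param fit A [quiescence()] fit.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "quiescence"))
  rep <- list(
    timepoints_pct = as.list(fit$t_pct),
    timepoints_ms = as.list(fit$t_ms),
    intervals = lapply(fit$intervals, function(iv)
      iv[c("start_pct", "end_pct", "duration_pct", "duration_ms",
           "tau_pct", "capped")]),
    mean_rr_ms = fit$mean_rr_ms,
    n_beats = length(fit$beats$rr_ms),
    beat_source = fit$beat_source,
    selected_fraction = as.list(fit$windows$selected_fraction),
    regions = fit$sync$regions,
    control = fit$control[c("n_frames", "kernel_pct", "top_region_fraction",
                            "amplitude_threshold_pct", "max_interval_ms",
                            "threshold_step_pct")])
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
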