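#' Write a CEST/WASSR series as NIfTI + JSON sidecar
#'
#' The 4-D signal array is written as \code{<prefix>.nii.gz} and the offset
#' list and reference index as \code{<prefix>.json}
#' (\code{{"offsets_ppm": [...], "reference_index": i}}).
#'
#' @param series a \code{\link{cest_series}} / \code{wassr_series}.
#' @param prefix output path without extension.
#' @param voxel_mm voxel size in mm (written to the NIfTI header).
#' @return the prefix, invisibly.
#' @export
write_cest_nifti <- function(series, prefix, voxel_mm = c(0.6, 0.6, 5)) {
  stopifnot(inherits(series, "cest_series"))
  img <- RNifti::asNifti(series$volumes,
                         pixdim = c(voxel_mm, 1))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(offsets_ppm = series$offsets,
                            reference_index = series$reference_index),
                       paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a CEST/WASSR series from NIfTI + JSON sidecar
#'
#' @param prefix path prefix as used by \code{\link{write_cest_nifti}}.
#' @param wassr return a \code{wassr_series} (validates grid symmetry).
#' @return a \code{\link{cest_series}} or \code{wassr_series}.
#' @export
read_cest_nifti <- function(prefix, wassr = FALSE) {
  vol <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ctor <- if (wassr) wassr_series else cest_series
  ctor(vol, side$offsets_ppm, side$reference_index)
}

#' Write a voxel map (e.g. MTR_asym, B0, T1) as NIfTI
#'
#' @param map numeric array (2-D or 3-D).
#' @param path output file (.nii or .nii.gz).
#' @param voxel_mm voxel size in mm.
#' @return the path, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_mm = c(0.6, 0.6, 5)) {
  if (length(dim(map)) == 2L) dim(map) <- c(dim(map), 1L)
  RNifti::writeNifti(RNifti::asNifti(map, pixdim = voxel_mm), path)
  invisible(path)
}

#' Write a phantom dataset to a directory
#'
#' Produces the same on-disk layout expected of real data: CEST and WASSR
#' series with JSON sidecars, relaxometry series with time-list sidecars, the
#' ROI mask, and the ground-truth maps under \code{truth_*}.
#'
#' @param ds a \code{phantom_dataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_phantom <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cest_nifti(ds$cest, file.path(dir, "cest"))
  write_cest_nifti(ds$wassr, file.path(dir, "wassr"))
  write_map_nifti(ds$roi$mask * 1, file.path(dir, "roi.nii.gz"))
  for (nm in c("t1_series", "t2_series")) {
    s <- ds[[nm]]
    write_map_nifti(s$volumes, file.path(dir, paste0(nm, ".nii.gz")))
    jsonlite::write_json(list(times_ms = s$times_ms),
                         file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  for (nm in c("b0_ppm", "mtr_asym_pct", "t1_ms", "t2_ms"))
    write_map_nifti(ds$truth[[nm]], file.path(dir, paste0("truth_", nm, ".nii.gz")))
  invisible(dir)
}

#' Write a z-spectrum or sweep result as CSV
#'
#' @param x a \code{zspectrum}, \code{mtr_asym_curve} or data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_csv_result <- function(x, path) {
  df <- if (inherits(x, "zspectrum"))
    data.frame(offset_ppm = x$offsets, z = x$z)
  else if (inherits(x, "mtr_asym_curve"))
    data.frame(offset_ppm = x$offsets, mtr_asym_pct = x$percent)
  else as.data.frame(x)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
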