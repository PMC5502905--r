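## File interfaces: NIfTI volumes (echo stacks, parameter maps, masks) with
## JSON sidecars for acquisition metadata, and CSV tables for per-slice and
## per-plaque measurements.

#' Write / read a multi-echo series as NIfTI plus JSON sidecar
#'
#' The echo dimension is stored as the 4th axis of a single NIfTI volume;
#' echo times and slice geometry go to a JSON sidecar next to it.
#'
#' @param series An [echo_series()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @param tr_ms Repetition time recorded in the sidecar, ms.
#' @param seed Optional seed recorded in the sidecar.
#' @return Invisibly, the NIfTI path.
#' @export
write_echo_series <- function(series, prefix, tr_ms = 2000, seed = NULL) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)
  vol <- array(series$data, c(d[1], d[2], 1L, d[3]))
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(vol, nii)
  side <- list(echo_times_ms = series$echo_times, tr_ms = tr_ms,
               slice_thickness_mm = series$slice_thickness,
               voxel_area_mm2 = series$voxel_area,
               slice_index = series$slice_index)
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(nii)
}

#' @rdname write_echo_series
#' @export
read_echo_series <- function(prefix) {
  vol <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  d <- dim(vol)
  echo_series(array(as.array(vol), c(d[1], d[2], d[4])),
              echo_times = side$echo_times_ms,
              slice_index = side$slice_index %||% 1L,
              voxel_area = side$voxel_area_mm2 %||% 0.04,
              slice_thickness = side$slice_thickness_mm %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a binary mask as uint8 NIfTI
#'
#' @param mask Logical matrix.
#' @param path Output `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)), datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  as.array(RNifti::readNifti(path)) > 0
}

#' Write a fitted T2 map as NIfTI volumes
#'
#' Emits `<prefix>_t2.nii.gz`, `<prefix>_s0.nii.gz`, `<prefix>_rsq.nii.gz`
#' and `<prefix>_valid.nii.gz`.
#'
#' @param t2map A [fit_slice()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the T2 map path.
#' @export
write_t2map <- function(t2map, prefix) {
  stopifnot(inherits(t2map, "t2map"))
  RNifti::writeNifti(t2map$t2, paste0(prefix, "_t2.nii.gz"))
  RNifti::writeNifti(t2map$s0, paste0(prefix, "_s0.nii.gz"))
  RNifti::writeNifti(t2map$rsq, paste0(prefix, "_rsq.nii.gz"))
  write_mask(t2map$valid, paste0(prefix, "_valid.nii.gz"))
  invisible(paste0(prefix, "_t2.nii.gz"))
}
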