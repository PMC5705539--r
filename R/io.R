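#' Read / write voxel grids as NIfTI-1 volumes
#'
#' Volumes are stored as NIfTI-1 with the voxel size in the pixdim header
#' fields; the unit tag travels in a JSON sidecar next to the image
#' (`img.nii` -> `img.json`). Round trips are lossless in values, voxel
#' size and unit. A missing sidecar reads back with unit `"unknown"` and
#' a warning.
#'
#' @param grid A [voxel_grid()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   a [voxel_grid()].
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(unit = grid$unit, voxel_size_mm = grid$voxel_size_mm),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vox)) || any(vox <= 0)) {
    stop("NIfTI header lacks valid voxel dimensions")
  }
  unit <- "unknown"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$unit)) unit <- meta$unit
  } else {
    warning("no unit sidecar found; unit set to 'unknown'")
  }
  voxel_grid(array(as.numeric(img), dim = dim(img)[1:3]), vox, unit = unit)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read / write VOI masks as 8-bit 0/1 NIfTI volumes
#'
#' @param mask A [voi_mask()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_mask` returns `path` invisibly; `read_mask` a
#'   [voi_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$values), dim = dim(mask$values)))
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vox)) || any(vox <= 0)) {
    stop("NIfTI header lacks valid voxel dimensions")
  }
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  if (!all(vals %in% c(0, 1))) stop("mask file contains values other than 0/1")
  voi_mask(vals, vox)
}

#' Read / write dose kernels (NIfTI array + JSON sidecar)
#'
#' The S-value array is stored as NIfTI; the sidecar records the voxel
#' size, the unit (`Gy/decay`), the mean energy per decay and the
#' declared leakage fraction, so the energy-closure check re-runs on read.
#'
#' @param kernel A [dose_kernel()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_kernel` returns `path` invisibly; `read_kernel` a
#'   [dose_kernel()].
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "dose_kernel"))
  img <- RNifti::asNifti(kernel$svalues)
  RNifti::pixdim(img) <- kernel$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(unit = "Gy/decay", voxel_size_mm = kernel$voxel_size_mm,
         energy_per_decay_J = kernel$energy_per_decay_J,
         leakage = kernel$leakage),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("kernel sidecar JSON not found: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  dose_kernel(array(as.numeric(img), dim = dim(img)[1:3]),
              meta$voxel_size_mm, meta$energy_per_decay_J,
              leakage = meta$leakage)
}

#' Read / write recovery-coefficient tables as CSV
#'
#' Column headers `volume_mL, rc`.
#'
#' @param table An [recovery_coefficients()] table.
#' @param path CSV path.
#' @return `write_rc_table` returns `path` invisibly; `read_rc_table` an
#'   `rc_table`.
#' @export
write_rc_table <- function(table, path) {
  stopifnot(inherits(table, "rc_table"))
  utils::write.csv(data.frame(volume_mL = table$volume_ml, rc = table$rc),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rc_table
#' @export
read_rc_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("volume_mL", "rc") %in% names(df))) {
    stop("RC table needs columns volume_mL, rc")
  }
  recovery_coefficients(df$rc, 1, df$volume_mL)
}
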