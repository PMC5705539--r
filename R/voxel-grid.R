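#' 3D scalar field on a regular voxel grid
#'
#' The basic image container: a 3D numeric array with anisotropic voxel
#' dimensions (mm) and a unit tag. Activity-concentration images carry
#' `"Bq/mL"`, dose maps `"Gy"`, raw count fields `"counts"`.
#'
#' Coordinate convention: voxel indices are 1-based in R; world coordinates
#' are in mm with the origin at the grid corner, so the centre of voxel
#' `(i, j, k)` sits at `((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz)`.
#'
#' @param values 3D numeric array (all finite).
#' @param voxel_size_mm Length-3 positive numeric: voxel edge lengths in mm.
#' @param unit Unit tag, one of `"Bq/mL"`, `"Gy"`, `"counts"`, `"unknown"`.
#'
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size_mm, unit = c("Bq/mL", "Gy", "counts", "unknown")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array")
  }
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("`values` must be finite")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive lengths")
  }
  if (unit == "counts" && any(values < 0)) {
    stop("count fields cannot be negative")
  }
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm, unit = unit),
    class = "voxel_grid"
  )
}

#' Voxel volume in mL
#'
#' `prod(voxel_size_mm) / 1000` (1 mL = 1000 mm^3). With unit density
#' (1 g/cm^3) this is numerically the voxel mass in grams.
#'
#' @param grid A [voxel_grid()] or voi_mask.
#' @return Voxel volume in mL (strictly positive).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, c("voxel_grid", "voi_mask")))
  prod(grid$voxel_size_mm) / 1000
}

#' Binary volume-of-interest mask
#'
#' A logical 3D array sharing a [voxel_grid()]'s geometry. All VOI
#' statistics, histograms and DVHs are computed over the `TRUE` voxels.
#'
#' @param values Logical (or 0/1 numeric) 3D array.
#' @param voxel_size_mm Length-3 positive numeric, mm.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, voxel_size_mm) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("mask `values` must be a 3D array")
  }
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1))) stop("numeric mask must be 0/1")
    values <- array(values > 0.5, dim = dim(values))
  }
  stopifnot(is.logical(values))
  values[is.na(values)] <- FALSE
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive lengths")
  }
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm),
    class = "voi_mask"
  )
}

#' Mask volume in mL
#'
#' Number of `TRUE` voxels times the voxel volume.
#'
#' @param mask A [voi_mask()].
#' @return Volume in mL.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$values) * voxel_volume_ml(mask)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels of %.4g x %.4g x %.4g mm [%s]; range [%.4g, %.4g]\n",
    d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    x$unit, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voi_mask> %d x %d x %d voxels; %d in mask (%.4g mL)\n",
    d[1], d[2], d[3], sum(x$values), mask_volume_ml(x)
  ))
  invisible(x)
}

# Internal: check image/mask share geometry; mask non-empty when required.
check_geometry <- function(image, mask, require_nonempty = TRUE) {
  stopifnot(inherits(image, "voxel_grid"), inherits(mask, "voi_mask"))
  if (!identical(dim(image$values), dim(mask$values)) ||
      max(abs(image$voxel_size_mm - mask$voxel_size_mm)) > 1e-9) {
    stop("image and mask geometries differ")
  }
  if (require_nonempty && !any(mask$values)) stop("mask is empty")
  invisible(TRUE)
}

# Internal: masked voxel values as a vector.
masked_values <- function(image, mask) {
  check_geometry(image, mask)
  image$values[mask$values]
}
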