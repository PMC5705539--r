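#' Phantom compartment
#'
#' One geometric primitive filled with a uniform activity concentration.
#' Cylinders are axis-aligned along z; `dim_mm` is interpreted per shape:
#' cylinder `c(diameter, height)`, sphere `diameter`, box
#' `c(lx, ly, lz)` edge lengths.
#'
#' @param name Compartment name (used for the returned mask and in errors).
#' @param shape One of `"cylinder"`, `"sphere"`, `"box"`.
#' @param center_mm Length-3 centre position in world mm (grid-corner origin).
#' @param dim_mm Shape dimensions in mm (see Description).
#' @param concentration_bq_ml Activity concentration, Bq/mL (>= 0).
#' @return An object of class `compartment`.
#' @export
compartment <- function(name, shape = c("cylinder", "sphere", "box"),
                        center_mm, dim_mm, concentration_bq_ml) {
  shape <- match.arg(shape)
  center_mm <- as.numeric(center_mm)
  dim_mm <- as.numeric(dim_mm)
  stopifnot(is.character(name), length(center_mm) == 3L, all(dim_mm > 0),
            concentration_bq_ml >= 0)
  nd <- switch(shape, cylinder = 2L, sphere = 1L, box = 3L)
  if (length(dim_mm) != nd) {
    stop(sprintf("shape '%s' needs %d dimension(s), got %d", shape, nd, length(dim_mm)))
  }
  structure(
    list(name = name, shape = shape, center_mm = center_mm,
         dim_mm = dim_mm, concentration_bq_ml = as.numeric(concentration_bq_ml)),
    class = "compartment"
  )
}

#' Phantom specification
#'
#' Grid geometry plus an ordered compartment list. Later compartments
#' overwrite earlier ones where they overlap (painter's order), so nested
#' structures are declared outside-in (e.g. liver, then a lesion insert).
#'
#' @param shape Integer triple: grid dimensions in voxels.
#' @param voxel_size_mm Length-3 voxel edge lengths, mm. The default
#'   `c(2.73, 2.73, 3.27)` matches a clinical PET reconstruction grid.
#' @param compartments List of [compartment()] objects, painter's order.
#' @param background_bq_ml Concentration outside all compartments, Bq/mL.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size_mm = c(2.73, 2.73, 3.27),
                         compartments = list(), background_bq_ml = 0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            background_bq_ml >= 0,
            all(vapply(compartments, inherits, logical(1), "compartment")))
  nm <- vapply(compartments, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("compartment names must be unique")
  structure(
    list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm),
         compartments = compartments, background_bq_ml = as.numeric(background_bq_ml)),
    class = "phantom_spec"
  )
}

# Axis-aligned world-mm bounding box of a compartment.
compartment_bbox <- function(comp) {
  half <- switch(comp$shape,
    cylinder = c(comp$dim_mm[1] / 2, comp$dim_mm[1] / 2, comp$dim_mm[2] / 2),
    sphere = rep(comp$dim_mm[1] / 2, 3),
    box = comp$dim_mm / 2
  )
  rbind(lo = comp$center_mm - half, hi = comp$center_mm + half)
}

# Point-membership test, vectorized over an n x 3 matrix of world-mm points.
compartment_contains <- function(comp, pts) {
  d <- sweep(pts, 2, comp$center_mm)
  switch(comp$shape,
    cylinder = (d[, 1]^2 + d[, 2]^2 <= (comp$dim_mm[1] / 2)^2) &
               (abs(d[, 3]) <= comp$dim_mm[2] / 2),
    sphere = rowSums(d^2) <= (comp$dim_mm[1] / 2)^2,
    box = abs(d[, 1]) <= comp$dim_mm[1] / 2 &
          abs(d[, 2]) <= comp$dim_mm[2] / 2 &
          abs(d[, 3]) <= comp$dim_mm[3] / 2
  )
}

# Fractional voxel occupancy of one compartment by s^3 sub-voxel sampling.
# Returns a full-grid array of occupancies in [0, 1].
compartment_occupancy <- function(comp, shape, voxel_size_mm, subsample = 3L) {
  occ <- array(0, dim = shape)
  bbox <- compartment_bbox(comp)
  grid_hi <- shape * voxel_size_mm
  if (any(bbox["lo", ] < -1e-9) || any(bbox["hi", ] > grid_hi + 1e-9)) {
    stop(sprintf("compartment '%s' extends outside the grid", comp$name))
  }
  # voxel index window overlapping the bounding box
  i0 <- pmax(1L, floor(bbox["lo", ] / voxel_size_mm) + 1L)
  i1 <- pmin(shape, ceiling(bbox["hi", ] / voxel_size_mm))
  if (any(i0 > i1)) return(occ)

  idx <- as.matrix(expand.grid(x = i0[1]:i1[1], y = i0[2]:i1[2], z = i0[3]:i1[3]))
  s <- as.integer(subsample)
  frac_off <- (2 * seq_len(s) - 1) / (2 * s) # sub-voxel centres in (0,1)
  offs <- as.matrix(expand.grid(x = frac_off, y = frac_off, z = frac_off))

  inside <- numeric(nrow(idx))
  for (o in seq_len(nrow(offs))) {
    pts <- sweep(idx - 1L, 2, offs[o, ], "+")
    pts <- sweep(pts, 2, voxel_size_mm, "*")
    inside <- inside + compartment_contains(comp, pts)
  }
  occ[idx] <- inside / nrow(offs)
  occ
}

#' Rasterize a phantom specification
#'
#' Paints compartments onto the grid in order, blending by fractional
#' sub-voxel occupancy so edge voxels carry volume-weighted concentrations.
#' Each compartment also yields a binary mask (occupancy >= 0.5), with
#' voxels claimed by a later overlapping compartment removed, so nested
#' structures produce disjoint masks.
#'
#' @param spec A [phantom_spec()].
#' @param subsample Sub-voxel sampling factor per axis (default 3, i.e.
#'   27 sample points per voxel).
#' @return A list with `activity` (a Bq/mL [voxel_grid()]) and `masks`
#'   (named list of [voi_mask()], one per compartment).
#' @export
build_phantom <- function(spec, subsample = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  vals <- array(spec$background_bq_ml, dim = spec$shape)
  nc <- length(spec$compartments)
  occs <- vector("list", nc)
  for (i in seq_len(nc)) {
    occs[[i]] <- compartment_occupancy(spec$compartments[[i]], spec$shape,
                                       spec$voxel_size_mm, subsample)
    f <- occs[[i]]
    vals <- vals * (1 - f) + spec$compartments[[i]]$concentration_bq_ml * f
  }
  masks <- list()
  for (i in seq_len(nc)) {
    m <- occs[[i]] >= 0.5
    j <- i + 1L
    while (j <= nc) {
      m <- m & !(occs[[j]] >= 0.5)
      j <- j + 1L
    }
    masks[[spec$compartments[[i]]$name]] <-
      voi_mask(array(m, dim = spec$shape), spec$voxel_size_mm)
  }
  list(
    activity = voxel_grid(vals, spec$voxel_size_mm, unit = "Bq/mL"),
    masks = masks
  )
}

#' Uniform cylindrical calibration phantom
#'
#' A 5640 mL cylinder uniformly filled with activity, used to validate the
#' PET calibration factor: diameter 200 mm, height chosen so the analytic
#' volume is exactly 5640 mL.
#'
#' @param concentration_bq_ml Fill concentration, Bq/mL (default 273 kBq/mL).
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @param margin_mm Empty margin around the cylinder on every side.
#' @return A [phantom_spec()] with a single compartment `"cylinder"`.
#' @export
phantom_uniform_cylinder <- function(concentration_bq_ml = 273e3,
                                     voxel_size_mm = c(2.73, 2.73, 3.27),
                                     margin_mm = 15) {
  d <- 200
  h <- 5640e3 / (pi * (d / 2)^2)
  extent <- c(d, d, h) + 2 * margin_mm
  shape <- ceiling(extent / voxel_size_mm)
  center <- shape * voxel_size_mm / 2
  phantom_spec(
    shape = shape, voxel_size_mm = voxel_size_mm,
    compartments = list(
      compartment("cylinder", "cylinder", center, c(d, h), concentration_bq_ml)
    )
  )
}

#' Volumes (mL) of the six IEC body-phantom spheres
#' @export
IEC_SPHERE_VOLUMES_ML <- c(0.52, 1.15, 2.57, 5.57, 11.49, 26.52)

#' IEC body phantom with six hot spheres
#'
#' Six fillable spheres (0.52 to 26.52 mL) on a 114.4 mm diameter circle
#' inside a cylindrical background compartment, with an 8:1
#' sphere-to-background concentration ratio by default. Used to measure
#' recovery coefficients for partial-volume correction.
#'
#' @param sphere_bq_ml Sphere concentration, Bq/mL (default 2.28 MBq/mL).
#' @param ratio Sphere-to-background concentration ratio (default 8).
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @return A [phantom_spec()]; sphere compartments are named
#'   `"sphere_<volume>mL"`.
#' @export
phantom_iec_body <- function(sphere_bq_ml = 2.28e6, ratio = 8,
                             voxel_size_mm = c(2.73, 2.73, 3.27)) {
  bg_d <- 230
  bg_h <- 180
  extent <- c(bg_d, bg_d, bg_h) + 2 * 12
  shape <- ceiling(extent / voxel_size_mm)
  center <- shape * voxel_size_mm / 2
  comps <- list(
    compartment("background", "cylinder", center, c(bg_d, bg_h), sphere_bq_ml / ratio)
  )
  r_ring <- 57.2
  angles <- (seq_along(IEC_SPHERE_VOLUMES_ML) - 1) * pi / 3
  for (i in seq_along(IEC_SPHERE_VOLUMES_ML)) {
    v <- IEC_SPHERE_VOLUMES_ML[i]
    dia <- 2 * (3 * v * 1000 / (4 * pi))^(1 / 3)
    ctr <- center + c(r_ring * cos(angles[i]), r_ring * sin(angles[i]), 0)
    comps[[i + 1L]] <- compartment(sprintf("sphere_%.2fmL", v), "sphere",
                                   ctr, dia, sphere_bq_ml)
  }
  phantom_spec(shape = shape, voxel_size_mm = voxel_size_mm, compartments = comps)
}

#' Anthropomorphic torso phantom with a hepatic lesion insert
#'
#' A 13.7 L torso compartment holding a 1200 mL liver, two cold lungs
#' (900 and 1100 mL), a cold 200 mL spine insert, and a cylindrical
#' "lesion" insert (diameter 28.5 mm, height 30 mm, nominal volume
#' 19.13 mL) fixed inside the liver. The torso water is non-radioactive;
#' the default insert-to-liver concentration ratio is about 6:1
#' (5.5 vs 0.89 MBq/mL, the day-1 study condition).
#'
#' @param insert_bq_ml Insert concentration, Bq/mL.
#' @param liver_bq_ml Liver concentration, Bq/mL.
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @return A [phantom_spec()] with compartments `"body"`, `"liver"`,
#'   `"lung_left"`, `"lung_right"`, `"spine"`, `"insert"`.
#' @export
phantom_anthropomorphic <- function(insert_bq_ml = 5.5e6, liver_bq_ml = 0.89e6,
                                    voxel_size_mm = c(2.73, 2.73, 3.27)) {
  extent <- c(320, 240, 200)
  shape <- ceiling(extent / voxel_size_mm)
  # body box volume minus organs leaves ~10.3 L of cold background water
  comps <- list(
    compartment("body", "box", c(160, 120, 100), c(300, 228, 200), 0),
    compartment("liver", "box", c(90, 70, 100), c(150, 100, 80), liver_bq_ml),
    compartment("lung_left", "cylinder", c(90, 180, 100),
                c(80, 900e3 / (pi * 40^2)), 0),
    compartment("lung_right", "cylinder", c(230, 180, 100),
                c(85, 1100e3 / (pi * 42.5^2)), 0),
    compartment("spine", "cylinder", c(230, 70, 100),
                c(40, 200e3 / (pi * 20^2)), 0),
    compartment("insert", "cylinder", c(90, 70, 100), c(28.5, 30), insert_bq_ml)
  )
  phantom_spec(shape = shape, voxel_size_mm = voxel_size_mm, compartments = comps)
}
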