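# Shared tiny fixtures for the test suite. All fixtures are built in code.

PET_VOX <- c(2.73, 2.73, 3.27)

# A small grid with the given constant value.
constant_grid <- function(value, dims = c(4, 4, 4), vox = PET_VOX,
                          unit = "Bq/mL") {
  voxel_grid(array(value, dim = dims), vox, unit = unit)
}

# A full mask over the same dims.
full_mask <- function(dims = c(4, 4, 4), vox = PET_VOX) {
  voi_mask(array(TRUE, dim = dims), vox)
}

# A grid holding the given values (recycled), with a full mask.
grid_with_values <- function(values, vox = PET_VOX, unit = "Bq/mL") {
  n <- length(values)
  g <- voxel_grid(array(values, dim = c(n, 1, 1)), vox, unit = unit)
  list(grid = g, mask = voi_mask(array(TRUE, dim = c(n, 1, 1)), vox))
}

# Small uniform cylinder phantom for simulation tests: cylinder plus a
# concentric interior VOI kept clear of the wall.
small_cylinder_phantom <- function(conc = 1e6, vox = PET_VOX,
                                   d_mm = 50, h_mm = 50,
                                   voi_d_mm = 24, voi_h_mm = 24,
                                   margin_mm = 18) {
  extent <- c(d_mm, d_mm, h_mm) + 2 * margin_mm
  shape <- ceiling(extent / vox)
  center <- shape * vox / 2
  spec <- phantom_spec(
    shape = shape, voxel_size_mm = vox,
    compartments = list(
      compartment("cylinder", "cylinder", center, c(d_mm, h_mm), conc),
      compartment("voi", "cylinder", center, c(voi_d_mm, voi_h_mm), conc)
    )
  )
  build_phantom(spec)
}
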