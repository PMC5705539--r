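nuc <- y90_constants()

test_that("ld_constant reproduces the 90Y conversion constant", {
  expect_equal(ld_constant(nuc, rounded = TRUE),
               1.44 * 2.67 * 86400 * 0.932 * 1.602e-13 * 1000)
  # both time-integration conventions sit within 0.5% of 4.966e-5 Gy s mL
  expect_lt(abs(ld_constant(nuc, rounded = TRUE) - 4.966e-5) / 4.966e-5, 0.005)
  expect_lt(abs(ld_constant(nuc) - 4.966e-5) / 4.966e-5, 0.005)
  # 1/ln2 vs 1.44 differ by the documented 0.19%
  expect_equal(ld_constant(nuc) / ld_constant(nuc, rounded = TRUE),
               (1 / log(2)) / 1.44)

  # linear in half-life and mean energy
  nuc2 <- nuclide_constants(2 * nuc$half_life_s, 3 * nuc$mean_beta_energy_MeV,
                            nuc$max_beta_energy_MeV, nuc$branch_ratio_beta_plus)
  expect_equal(ld_constant(nuc2), 6 * ld_constant(nuc))
})

test_that("local deposition maps concentration to dose voxel-wise", {
  g <- constant_grid(1e6, dims = c(4, 4, 4))
  d <- local_deposition_dose(g, nuc)
  expect_equal(d$unit, "Gy")
  expect_true(all(d$values == 1e6 * ld_constant(nuc)))
  expect_equal(d$values[1, 1, 1], 49.7, tolerance = 0.001)

  d0 <- local_deposition_dose(constant_grid(0), nuc)
  expect_true(all(d0$values == 0))

  expect_error(local_deposition_dose(constant_grid(1, unit = "Gy"), nuc), "Bq/mL")
})

test_that("negative reconstructed voxels are clamped with a reported count", {
  vals <- array(c(-1, -2, rep(1e6, 6)), dim = c(2, 2, 2))
  g <- voxel_grid(vals, PET_VOX, "Bq/mL")
  expect_message(d <- local_deposition_dose(g, nuc), "2 negative")
  expect_true(all(d$values >= 0))
})

test_that("total deposited energy matches the permanent-implant integral", {
  set.seed(5)
  vals <- array(runif(4^3, 0, 1e6), dim = c(4, 4, 4))
  g <- voxel_grid(vals, PET_VOX, "Bq/mL")
  d <- local_deposition_dose(g, nuc)
  v_vox <- voxel_volume_ml(g)
  m_vox_kg <- v_vox * 1e-3
  e_total <- sum(d$values) * m_vox_kg
  a0_total <- sum(vals) * v_vox
  e_expected <- (1 / log(2)) * nuc$half_life_s * a0_total *
    nuc$mean_beta_energy_MeV * 1.602e-13
  expect_equal(e_total, e_expected)
})

test_that("MIRD average dose equals local deposition on uniform activity", {
  expect_equal(mird_average_dose(5.5e6, nuc, rounded = TRUE),
               5.5e6 * 4.966e-5, tolerance = 0.002)
  expect_equal(mird_average_dose(0, nuc), 0)
  g <- constant_grid(2.3e6, dims = c(5, 5, 5))
  d <- local_deposition_dose(g, nuc)
  m <- voi_mask(array(c(TRUE, FALSE), dim = c(5, 5, 5)), PET_VOX)
  expect_equal(dose_summary(d, m)$mean_gy, mird_average_dose(2.3e6, nuc))
})

test_that("dDVH integrates exactly to the mask volume", {
  cst <- constant_grid(10, dims = c(3, 3, 3), unit = "Gy")
  m <- full_mask(dims = c(3, 3, 3))
  dv <- ddvh(cst, m, bin_width = 2)
  expect_equal(sum(dv$dv_per_dD > 0), 1L)
  expect_equal(sum(dv$dv_per_dD * diff(dv$bin_edges)), mask_volume_ml(m))

  set.seed(11)
  for (bw in c(0.5, 1.7)) {
    vals <- array(rgamma(5^3, 3, 0.1), dim = c(5, 5, 5))
    d <- voxel_grid(vals, PET_VOX, "Gy")
    mask <- voi_mask(array(runif(5^3) > 0.4, dim = c(5, 5, 5)), PET_VOX)
    dv <- ddvh(d, mask, bin_width = bw)
    expect_equal(sum(dv$dv_per_dD * diff(dv$bin_edges)), mask_volume_ml(mask))
    # mean dose recomputed from bin midpoints agrees within half a bin
    mids <- dv$bin_edges[-1] - bw / 2
    mean_from_dvh <- sum(mids * dv$dv_per_dD) / sum(dv$dv_per_dD)
    expect_lt(abs(mean_from_dvh - mean(vals[mask$values])), bw / 2)
  }

  expect_error(ddvh(constant_grid(1), full_mask(), 1), "Gy")
})

test_that("dose_summary returns masked mean and population SD", {
  gv <- grid_with_values(c(0, 2))
  d <- voxel_grid(gv$grid$values, PET_VOX, "Gy")
  s <- dose_summary(d, gv$mask)
  expect_equal(s$mean_gy, 1)
  expect_equal(s$sd_gy, 1)
  cst <- dose_summary(constant_grid(4, unit = "Gy"), full_mask())
  expect_equal(cst$mean_gy, 4)
  expect_equal(cst$sd_gy, 0)
})

test_that("LD dose dispersion mirrors the activity homogeneity index", {
  ph <- small_cylinder_phantom(conc = 1e6)
  img <- simulate_pet(ph$activity, nuc, pet_acq_params(900, seed = 13))
  d <- local_deposition_dose(img, nuc)
  s <- dose_summary(d, ph$masks$voi)
  expect_equal(s$sd_gy / s$mean_gy, homogeneity_index(img, ph$masks$voi))
})
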