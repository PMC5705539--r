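nuc <- y90_constants()

test_that("calibration factor rescales a surrogate factor by the branch ratio", {
  expect_equal(calibration_factor_y90(5, 1), 5)
  expect_equal(calibration_factor_y90(31.86, 3.186e-5), 1.0e6)
  expect_equal(calibration_factor_y90(2 * 31.86, 3.186e-5),
               2 * calibration_factor_y90(31.86, 3.186e-5))
  expect_error(calibration_factor_y90(1, 0), "branch_ratio")
})

test_that("voi_stats follows the linear-interpolation quantile convention", {
  gv <- grid_with_values(c(1, 2, 3, 4))
  st <- voi_stats(gv$grid, gv$mask)
  expect_equal(st$mean, 2.5)
  expect_equal(st$q1, 1.75)
  expect_equal(st$q3, 3.25)
  expect_equal(st$min, 1)
  expect_equal(st$max, 4)

  cst <- voi_stats(constant_grid(7), full_mask())
  expect_equal(cst$mean, 7)
  expect_equal(cst$q1, 7)
  expect_equal(cst$q3, 7)
  expect_equal(cst$sd, 0)
  expect_equal(cst$skewness, 0) # degenerate skewness reported as 0
})

test_that("sample skewness is the adjusted Fisher-Pearson coefficient", {
  x <- c(1, 2, 3, 10)
  n <- length(x)
  g1 <- mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  expect_equal(sample_skewness(x), g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_equal(sample_skewness(c(2, 2)), 0)
})

test_that("dAVH integrates to one and splits mass by volume fraction", {
  cst <- davh(constant_grid(5), full_mask())
  expect_equal(sum(cst$density * diff(cst$bin_edges)), 1)
  expect_equal(sum(cst$density > 0), 1L)

  gv <- grid_with_values(c(1, 1, 3, 3))
  h <- davh(gv$grid, gv$mask, bin_width = 1)
  expect_equal(sum(h$density * diff(h$bin_edges)), 1)
  occupied <- which(h$density > 0)
  expect_length(occupied, 2L)
  expect_equal(h$density[occupied[1]], h$density[occupied[2]])

  # normalization holds for arbitrary images and bin widths
  set.seed(314)
  for (bw in c(0.01, 0.37, 2)) {
    gv <- grid_with_values(rlnorm(200))
    h <- davh(gv$grid, gv$mask, bin_width = bw)
    expect_lt(abs(sum(h$density * diff(h$bin_edges)) - 1), 1e-9)
  }
})

test_that("homogeneity index is the volume-weighted CV", {
  expect_equal(homogeneity_index(constant_grid(3), full_mask()), 0)

  gv <- grid_with_values(c(0, 2))
  expect_equal(homogeneity_index(gv$grid, gv$mask), 1)

  set.seed(21)
  gv <- grid_with_values(rgamma(100, 4))
  hi <- homogeneity_index(gv$grid, gv$mask)
  x <- gv$grid$values
  # equal voxel volumes: HI = population sd / mean
  expect_equal(hi, sqrt(mean((x - mean(x))^2)) / mean(x))
  # scale invariance
  gv2 <- grid_with_values(7.3 * as.vector(x))
  expect_equal(homogeneity_index(gv2$grid, gv2$mask), hi)

  gv0 <- grid_with_values(c(0, 0))
  expect_error(homogeneity_index(gv0$grid, gv0$mask), "mean")
})

test_that("recovery coefficients are measured/true sorted by volume", {
  tab <- recovery_coefficients(c(2.28e6, 0.456e6), 2.28e6, c(26.52, 0.52))
  expect_s3_class(tab, "rc_table")
  expect_equal(tab$volume_ml, c(0.52, 26.52))
  expect_equal(tab$rc, c(0.2, 1))
  expect_error(recovery_coefficients(1, 0, 1), "true_conc")
})

test_that("pve_correct divides by the log-volume-interpolated RC with clamping", {
  tab <- recovery_coefficients(c(0.2, 0.5, 0.811, 0.86) * 100, 100,
                               c(0.52, 2.57, 11.49, 26.52))
  # identity when RC = 1
  one <- recovery_coefficients(c(100, 100), 100, c(1, 10))
  expect_equal(pve_correct(4.3, 5, one), 4.3)
  # at a tabulated volume: plain division (Table-2-style arithmetic)
  expect_equal(pve_correct(4.30, 11.49, tab), 4.30 / 0.811)
  # interpolation is linear in log(volume)
  v_mid <- exp(mean(log(c(2.57, 11.49))))
  expect_equal(pve_correct(1, v_mid, tab), 1 / mean(c(0.5, 0.811)))
  # clamped below the smallest and above the largest tabulated volume
  expect_equal(pve_correct(1, 0.1, tab), 1 / 0.2)
  expect_equal(pve_correct(1, 100, tab), 1 / 0.86)
  # correcting after multiplying by RC is the identity at tabulated volumes
  for (i in seq_len(nrow(tab))) {
    expect_equal(pve_correct(5 * tab$rc[i], tab$volume_ml[i], tab), 5)
  }
  expect_error(pve_correct(1, 1, recovery_coefficients(1, 1, 1)), "2 rows")
})

test_that("percent deviation reproduces tabulated comparisons", {
  expect_equal(round(percent_deviation(257, 273), 1), -5.9)
  expect_equal(percent_deviation(5, 5), 0)
  expect_equal(round(percent_deviation(0.19, 0.24), 1), -20.8)
  expect_error(percent_deviation(1, 0), "non-zero")
})

test_that("emitted positrons apply branch ratio and decay-corrected time", {
  expect_equal(emitted_positrons(1e6, 10, nuc, 0), 0)
  zero_br <- nuclide_constants(nuc$half_life_s, nuc$mean_beta_energy_MeV,
                               nuc$max_beta_energy_MeV, 1e-300)
  expect_equal(emitted_positrons(1e6, 10, zero_br, 900), 0, tolerance = 1e-12)

  # closed form: 5.5 MBq/mL, 19.13 mL, 900 s -> ~3.01e6 positrons
  lam <- log(2) / nuc$half_life_s
  expected <- 5.5e6 * 19.13 * nuc$branch_ratio_beta_plus * (1 - exp(-lam * 900)) / lam
  expect_equal(emitted_positrons(5.5e6, 19.13, nuc, 900), expected)
  expect_equal(expected, 3.01e6, tolerance = 0.002)
  # decay correction stays below 0.2% over 15 min
  expect_lt(1 - expected / (5.5e6 * 19.13 * nuc$branch_ratio_beta_plus * 900), 0.002)
})
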