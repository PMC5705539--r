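nuc <- y90_constants()

test_that("the measurement equation is strictly multiplicative", {
  r <- tld_reading(tl_signal = 120, n_dw = 2.5e-3)
  expect_equal(tld_dose(r)$dose_gy, 120 * 2.5e-3)

  r2 <- tld_reading(120, 2.5e-3, k_fv = 1.04, h = 0.97, k_mat = 1.02)
  d2 <- tld_dose(r2)$dose_gy
  expect_equal(d2, 120 * 2.5e-3 * 1.04 * 0.97 * 1.02)
  # doubling any factor doubles the dose
  r3 <- tld_reading(120, 2.5e-3, k_fv = 1.04, h = 0.97, k_mat = 2 * 1.02)
  expect_equal(tld_dose(r3)$dose_gy, 2 * d2)
  # log-domain sum equals the product to machine precision
  expect_equal(log(d2), log(120) + log(2.5e-3) + log(1.04) + log(0.97) + log(1.02))
})

test_that("relative uncertainties combine in quadrature", {
  r <- tld_reading(100, 1e-3, u_tl_rel = 0.02, u_n_dw_rel = 0.01,
                   u_k_fv_rel = 0.01, u_h_rel = 0.02, u_k_mat_rel = 0.01)
  expect_equal(tld_dose(r)$rel_u, sqrt(0.02^2 + 0.01^2 + 0.01^2 + 0.02^2 + 0.01^2))
  expect_equal(round(tld_dose(r)$rel_u, 4), 0.0332)
})

test_that("contaminated chips are rejected with a reason", {
  r <- tld_reading(100, 1e-3, contaminated = TRUE)
  expect_error(tld_dose(r), "contaminated")
})

test_that("chip aggregation is inverse-variance weighting", {
  # equal absolute uncertainties reduce to the arithmetic mean
  eq <- aggregate_chips(c(1, 2, 3), 0.05 / c(1, 2, 3))
  expect_equal(eq$dose_gy, 2)

  d <- c(1.0, 1.1, 1.2) * 1e-11
  u <- c(0.05, 0.05, 0.10)
  got <- aggregate_chips(d, u)
  w <- 1 / (d * u)^2
  expect_equal(got$dose_gy, sum(w * d) / sum(w))
  expect_equal(got$u_gy, sqrt(1 / sum(w)))
  # the aggregate is never more uncertain than the best chip
  expect_lte(got$u_gy, min(d * u))

  # a chip with 100x the uncertainty carries < 0.01% of the weight
  d2 <- c(1, 1.5) * 1e-11
  u2 <- c(0.01, 1)
  got2 <- aggregate_chips(d2, u2)
  w2 <- 1 / (d2 * u2)^2
  expect_lt(w2[2] / sum(w2), 1e-4)
  expect_equal(got2$dose_gy, sum(w2 * d2) / sum(w2))

  # flags exclude chips up front; all-flagged errors
  fl <- aggregate_chips(c(1, 5, 1.1), c(0.05, 0.01, 0.05 / 1.1),
                        contaminated = c(FALSE, TRUE, FALSE))
  expect_equal(fl$dose_gy, mean(c(1, 1.1)))
  expect_equal(fl$excluded, 2L)
  expect_error(aggregate_chips(1, 0.1, contaminated = TRUE), "all chips")
})

test_that("opt-in Grubbs auto-flagging reports what it removes", {
  d <- c(rep(1.0, 7) + c(-0.02, 0.01, 0, 0.02, -0.01, 0.015, -0.005), 1.9)
  expect_message(
    got <- aggregate_chips(d, rep(0.05, 8), auto_flag = TRUE),
    "Grubbs"
  )
  expect_equal(got$excluded, 8L)
  expect_equal(got$n_used, 7L)
  # silent by default: no flagging without opt-in
  expect_silent(got_manual <- aggregate_chips(d, rep(0.05, 8)))
  expect_equal(got_manual$n_used, 8L)
})

test_that("dose per emitted particle divides by the decay-corrected emissions", {
  lam <- decay_constant(nuc)
  # 6.7 MBq/mL, 14.8 mL, 30 min: ~1.78e11 particles, decay correction ~0.16%
  got <- dose_per_emitted_particle(1.94, 6.7e6, 14.8, nuc, 1800)
  n_expected <- 6.7e6 * 14.8 * (1 - exp(-lam * 1800)) / lam
  expect_equal(got$n_particles, n_expected)
  expect_equal(n_expected / 1.78e11, 1, tolerance = 0.002)
  expect_equal(got$value, 1.94 / n_expected)
  expect_lt(1 - n_expected / (6.7e6 * 14.8 * 1800), 0.003)
  # uncertainty chain
  got_u <- dose_per_emitted_particle(1.94, 6.7e6, 14.8, nuc, 1800,
                                     rel_u_dw = 0.06, rel_u_conc = 0.01)
  expect_equal(got_u$rel_u, sqrt(0.06^2 + 0.01^2))
  expect_error(dose_per_emitted_particle(1, 0, 14.8, nuc, 1800), "positive")
})

test_that("the published uncertainty chain is representable", {
  # chips calibrated at 0.7-2.2% plus correction-factor uncertainties can
  # aggregate to a ~6% relative weighted standard uncertainty
  set.seed(53)
  n <- 10
  readings <- lapply(seq_len(n), function(i) {
    tld_reading(tl_signal = rnorm(1, 100, 8), n_dw = 1e-3,
                u_tl_rel = 0.15, u_n_dw_rel = runif(1, 0.007, 0.022),
                k_fv = 1.05, u_k_fv_rel = 0.03, h = 0.98, u_h_rel = 0.04,
                k_mat = 1.01, u_k_mat_rel = 0.02)
  })
  per <- lapply(readings, tld_dose)
  agg <- aggregate_chips(vapply(per, `[[`, numeric(1), "dose_gy"),
                         vapply(per, `[[`, numeric(1), "rel_u"))
  expect_gt(agg$rel_u, 0.01)
  expect_lt(agg$rel_u, 0.1)
})

test_that("chip tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    chip_id = c("A1", "A2", "A3"), tl_signal = c(100, 110, 500),
    n_dw = 1e-3, u_n_dw_rel = c(0.007, 0.022, 0.01),
    k_fv = 1.05, u_k_fv_rel = 0.03, h = 0.98, u_h_rel = 0.04,
    k_mat = 1.01, u_k_mat_rel = 0.02,
    contaminated = c(FALSE, FALSE, TRUE)
  )
  write.csv(df, path, row.names = FALSE)
  chips <- read_chip_table(path)
  expect_named(chips, c("A1", "A2", "A3"))
  expect_true(chips$A3$contaminated)
  expect_equal(chips$A2$u_n_dw_rel, 0.022)
  expect_error(tld_dose(chips$A3), "contaminated")
  expect_equal(tld_dose(chips$A1)$dose_gy, 100 * 1e-3 * 1.05 * 0.98 * 1.01)
})
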